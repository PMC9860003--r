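## Material attenuation: packaged 1-keV tables, K-edge-aware lookup, mixtures
## and dilute K-edge-agent solutions.

.pkgEnv <- new.env(parent = emptyenv())

.attenDir <- function() {
  d <- system.file("extdata", "attenuation", package = "pcctmd")
  if (!nzchar(d)) stop("packaged attenuation tables not found")
  d
}

.attenMeta <- function() {
  if (is.null(.pkgEnv$meta))
    .pkgEnv$meta <- jsonlite::read_json(file.path(.attenDir(),
                                                  "materials.json"))
  .pkgEnv$meta
}

## elemental mass attenuation (cm^2/g) for solutes, with its K-edge
.elementMass <- function(name) {
  key <- paste0("el_", name)
  if (is.null(.pkgEnv[[key]])) {
    f <- file.path(.attenDir(), paste0(name, "_element.csv"))
    if (!file.exists(f)) stop("unknown solute element: ", name)
    tab <- read.csv(f)
    meta <- .attenMeta()[[name]]
    .pkgEnv[[key]] <- list(mass = tab$mass_atten_cm2_per_g,
                           kEdges = unlist(meta$k_edges))
  }
  .pkgEnv[[key]]
}

.aliases <- c(tissue = "soft_tissue", bone = "cortical_bone",
              ptfe = "teflon", water = "water")

#' Look up or construct a material
#'
#' Resolves a material name to a [Material-class] with its packaged linear
#' attenuation table. Recognized names: `water`, `soft_tissue` (`tissue`),
#' `cortical_bone` (`bone`), `adipose`, `pmma`, `teflon`, `aluminum`, and
#' dilute solution names of the form `iodine_10mgml` / `gadolinium_10mgml`
#' (any concentration), which are built with [solutionMaterial()].
#'
#' @param name material identifier (case-insensitive).
#' @return A [Material-class] object.
#' @export
#' @examples
#' getMaterial("water")
#' getMaterial("gadolinium_10mgml")
getMaterial <- function(name) {
  if (is(name, "Material")) return(name)
  nm <- tolower(gsub("[ -]", "_", name))
  if (nm %in% names(.aliases)) nm <- .aliases[[nm]]
  m <- regmatches(nm, regexec("^(iodine|gadolinium)_?([0-9.]+)_?mg_?ml$", nm))[[1]]
  if (length(m) == 3L)
    return(solutionMaterial(m[2], as.numeric(m[3])))
  key <- paste0("mat_", nm)
  if (is.null(.pkgEnv[[key]])) {
    f <- file.path(.attenDir(), paste0(nm, ".csv"))
    if (!file.exists(f)) stop("unknown material name: ", name)
    tab <- read.csv(f)
    meta <- .attenMeta()[[nm]]
    .pkgEnv[[key]] <- new("Material", name = nm, mu = tab$mu_per_cm,
                          kEdges = as.numeric(unlist(meta$k_edges)))
  }
  .pkgEnv[[key]]
}

## Edge-aware nearest-bin index: round to the nearest 1-keV bin, but never
## across a tabulated K-edge, so the discontinuity sits at the edge energy.
.muIndex <- function(energy, kEdges) {
  idx <- as.integer(round(energy))
  idx[idx < 1L] <- 1L; idx[idx > .NE] <- .NE
  for (e in kEdges) {
    idx[energy > e & idx <= floor(e)] <- ceiling(e)
    idx[energy < e & idx >= ceiling(e)] <- floor(e)
  }
  idx
}

#' Linear attenuation coefficient of a material
#'
#' Nearest-bin lookup on the packaged 1-keV table. The lookup never rounds
#' across a K-edge: for energies between the edge and the adjacent bin center
#' the value from the correct side of the edge is returned, so the
#' discontinuity of the continuous-energy curve sits exactly at the tabulated
#' edge energy.
#'
#' @param material a [Material-class] or a name accepted by [getMaterial()].
#' @param energy energies in keV, each within [1, 140]; vectorized.
#' @return Linear attenuation per cm.
#' @export
#' @examples
#' attenuation("water", 60)
#' attenuation("gadolinium_10mgml", c(50.1, 50.3))  # straddles the K-edge
attenuation <- function(material, energy) {
  material <- getMaterial(material)
  if (any(energy < 1 | energy > .NE))
    stop("energy out of the [1, 140] keV grid")
  material@mu[.muIndex(energy, material@kEdges)]
}

#' Construct a mixture specification
#'
#' @param materials list of materials (or names).
#' @param fractions coefficient fractions, summing to 1.
#' @return A [MixtureSpec-class].
#' @export
mixtureSpec <- function(materials, fractions) {
  new("MixtureSpec", materials = lapply(materials, getMaterial),
      fractions = as.numeric(fractions))
}

#' Attenuation of a mixture
#'
#' Coefficient-weighted sum of the component attenuations,
#' `sum_i f_i mu_i(E)`.
#'
#' @param spec a [MixtureSpec-class].
#' @param energy energies in keV; vectorized.
#' @return Linear attenuation per cm.
#' @export
mixtureAttenuation <- function(spec, energy) {
  stopifnot(is(spec, "MixtureSpec"))
  validObject(spec)
  Reduce(`+`, Map(function(m, f) f * attenuation(m, energy),
                  spec@materials, spec@fractions))
}

#' Attenuation of a dilute solution
#'
#' Water plus the solute's elemental mass attenuation scaled by concentration:
#' `mu_water(E) + c[mg/ml] * 1e-3 [g/ml] * (mu/rho)_element(E)`. Water
#' displacement by the solute is neglected (dilute limit).
#'
#' @param solute `"iodine"` or `"gadolinium"`.
#' @param concentration solute concentration in mg/ml, >= 0.
#' @param energy energies in keV; vectorized.
#' @return Linear attenuation per cm.
#' @export
#' @examples
#' solutionAttenuation("iodine", 10, 70)
solutionAttenuation <- function(solute, concentration, energy) {
  attenuation(solutionMaterial(solute, concentration), energy)
}

#' Dilute solution as a Material
#'
#' @param solute `"iodine"` or `"gadolinium"`.
#' @param concentration mg/ml, >= 0.
#' @return A [Material-class] named e.g. `"iodine_10mgml"`.
#' @export
solutionMaterial <- function(solute, concentration) {
  if (concentration < 0) stop("concentration must be >= 0")
  key <- sprintf("sol_%s_%g", solute, concentration)
  if (is.null(.pkgEnv[[key]])) {
    el <- .elementMass(tolower(solute))
    water <- getMaterial("water")
    mu <- water@mu + concentration * 1e-3 * el$mass
    kE <- if (concentration > 0) el$kEdges else numeric()
    .pkgEnv[[key]] <- new("Material",
                          name = sprintf("%s_%gmgml", tolower(solute),
                                         concentration),
                          mu = mu, kEdges = as.numeric(kE))
  }
  .pkgEnv[[key]]
}

#' Locate K-edges by scanning an attenuation curve
#'
#' Scans the material's tabulated curve on the 1-keV grid for upward jumps
#' (the curve is otherwise non-increasing), then refines each jump position by
#' bisection on the continuous-energy lookup of [attenuation()].
#'
#' @param material a [Material-class] or name.
#' @param tol bisection tolerance in keV.
#' @return Numeric vector of edge energies in keV (empty if none).
#' @export
#' @examples
#' findKEdge("gadolinium_10mgml")  # 50.2
findKEdge <- function(material, tol = 1e-4) {
  material <- getMaterial(material)
  jumps <- which(diff(material@mu) > 0)
  vapply(jumps, function(j) {
    lo <- as.numeric(j); hi <- j + 1
    fLo <- attenuation(material, lo)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (attenuation(material, mid) > fLo) hi <- mid else lo <- mid
    }
    round((lo + hi) / 2, 6)
  }, numeric(1))
}

## 140 x P matrix of basis attenuation curves (bin-center values)
.muMatrix <- function(basis) {
  basis <- lapply(basis, getMaterial)
  mm <- vapply(basis, function(m) m@mu, numeric(.NE))
  colnames(mm) <- vapply(basis, materialName, character(1))
  mm
}
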