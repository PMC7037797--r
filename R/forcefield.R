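# Force-field parameter handling.  The backend is deliberately minimal:
# partial charges, one Lennard-Jones class per element, cosine torsion series
# and a configurable dielectric model.  All quantitative checks in the
# package are against closed forms and oracles, not absolute energies of any
# published force field.

COULOMB_CONST <- 332.0636  # kcal/mol * A / e^2

#' Read a force-field parameter file
#'
#' The file is YAML with sections `charges`, `lj`, `torsions` and
#' `dielectric`; see the packaged `forcefield_default.yaml` for the
#' documented key layout.
#'
#' @param path parameter file path.
#' @return a `forcefield` object (list with elements `charges`, `lj`,
#'   `torsions`, `dielectric`).
#' @export
read_forcefield <- function(path) {
  raw <- yaml::read_yaml(path)
  ff <- list(
    charges = unlist(raw$charges),
    lj = lapply(raw$lj, function(v) c(eps = v[[1]], rmin = v[[2]])),
    torsions = lapply(raw$torsions, function(terms) {
      do.call(rbind, lapply(terms, function(t) {
        data.frame(amplitude = t[[1]], periodicity = t[[2]], phase = t[[3]])
      }))
    }),
    dielectric = list(model = raw$dielectric$model %||% "distance",
                      coefficient = raw$dielectric$coefficient %||% 1))
  validate_forcefield(ff)
}

validate_forcefield <- function(ff) {
  if (any(vapply(ff$lj, function(v) v[["eps"]] < 0, logical(1)))) {
    abort("all Lennard-Jones well depths must be >= 0")
  }
  for (cls in names(ff$torsions)) {
    t <- ff$torsions[[cls]]
    if (!is.null(t) && any(t$periodicity < 1 | t$periodicity != round(t$periodicity))) {
      abort(sprintf("torsion class '%s' has a non-positive-integer periodicity", cls))
    }
  }
  if (!ff$dielectric$model %in% c("distance", "constant")) {
    abort("dielectric model must be 'distance' or 'constant'")
  }
  class(ff) <- "forcefield"
  ff
}

.ff_cache <- new.env(parent = emptyenv())

#' The packaged default force field
#'
#' Per-residue backbone charges, one Lennard-Jones class per element and
#' short cosine torsion series, with a distance-dependent dielectric
#' (eps(r) = r) as the default for conformational sampling.
#'
#' @return a `forcefield` object.
#' @export
default_forcefield <- function() {
  if (is.null(.ff_cache$default)) {
    .ff_cache$default <- read_forcefield(
      system.file("extdata", "forcefield_default.yaml", package = "helixcm"))
  }
  .ff_cache$default
}

#' Construct a force field in code
#'
#' @param charges named numeric vector keyed `"RES:ATOM"` (with `"*"`
#'   wildcards) in elementary charge units.
#' @param lj named list keyed by element, each `c(eps = , rmin = )`.
#' @param torsions named list of data frames with columns `amplitude`,
#'   `periodicity`, `phase`.
#' @param dielectric list with `model` (`"distance"` or `"constant"`) and
#'   `coefficient`.
#' @return a `forcefield` object.
#' @export
forcefield <- function(charges = c("*:*" = 0),
                       lj = list(),
                       torsions = list(),
                       dielectric = list(model = "distance", coefficient = 1)) {
  validate_forcefield(list(charges = charges, lj = lj, torsions = torsions,
                           dielectric = dielectric))
}

# Charge lookup with wildcard fallback; errors name the offending atom.
ff_charges <- function(ff, residue_name, atom) {
  keys1 <- paste0(residue_name, ":", atom)
  keys2 <- paste0("*:", atom)
  q <- ff$charges[keys1]
  q[is.na(q)] <- ff$charges[keys2][is.na(q)]
  q[is.na(q)] <- ff$charges["*:*"]
  if (anyNA(q)) {
    i <- which(is.na(q))[1]
    abort(sprintf("no partial charge for atom (%s, %s)",
                  residue_name[i], atom[i]))
  }
  unname(q)
}

ff_lj <- function(ff, element, residue_name = NULL, atom = NULL) {
  m <- ff$lj[element]
  if (any(vapply(m, is.null, logical(1)))) {
    i <- which(vapply(m, is.null, logical(1)))[1]
    where <- if (!is.null(atom)) sprintf(" (%s, %s)", residue_name[i], atom[i]) else ""
    abort(sprintf("no Lennard-Jones class for element %s%s", element[i], where))
  }
  list(eps = vapply(m, `[[`, 0, "eps"), rmin = vapply(m, `[[`, 0, "rmin"))
}
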