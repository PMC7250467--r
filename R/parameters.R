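# Parameter-set handling.  The YAML config file is the single source of
# truth: random-coil baselines, per-nucleus descriptor weights, Fourier
# coefficients for the phi/psi term, anisotropy constants, ring intensities
# and the geometric cutoffs all live there and round-trip losslessly.

PARAMS_FORMAT_VERSION <- 1L

ANI_KINDS <- c("backbone", "OCN", "OCO", "NCN")
FAMILIES <- c("contact", "hbond", "ani", "ring", "dihedral")

#' Read a parameter set from a YAML file
#'
#' @param path Path to a parameter file (see [default_params()] for the
#'   shipped defaults and the schema).
#' @return A validated `parameter_set`.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  as_parameter_set(raw)
}

#' Shipped default parameter set
#'
#' Random-coil baselines use literature random-coil shift tables; descriptor
#' weights default to 1 and Fourier coefficients to 0.  These defaults make
#' the predictor well-defined and fully exercisable, but quantitative
#' accuracy against experimental shifts requires refitting the weights with
#' [fit_parameters()] on observed data.
#'
#' @return A `parameter_set`.
#' @export
default_params <- function() {
  read_params(system.file("extdata", "default_params.yaml",
                          package = "pepshift", mustWork = TRUE))
}

as_parameter_set <- function(raw) {
  if (is.null(raw$format_version))
    stop("parameter file lacks a format_version key", call. = FALSE)
  if (raw$format_version != PARAMS_FORMAT_VERSION)
    stop(sprintf("unsupported parameter format_version %s",
                 raw$format_version), call. = FALSE)
  p <- list(
    format_version = PARAMS_FORMAT_VERSION,
    cutoffs = utils::modifyList(default_cutoffs(),
                                raw$cutoffs %||% list()),
    ring_scale = raw$ring_scale %||% 1.0,
    ring_intensity = raw$ring_intensity,
    delta_chi = raw$delta_chi,
    weights = raw$weights,
    fourier = raw$fourier,
    random_coil = raw$random_coil,
    ridge = raw$ridge %||% 0)
  validate_params(p)
  structure(p, class = "parameter_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_params <- function(p) {
  for (res in STANDARD_AA) {
    rc <- p$random_coil[[res]]
    if (is.null(rc) || !all(NUCLEI %in% names(rc)))
      stop(sprintf("random_coil table incomplete for %s", res), call. = FALSE)
  }
  for (nuc in NUCLEI) {
    w <- p$weights[[nuc]]
    if (is.null(w) || !all(FAMILIES %in% names(w)))
      stop(sprintf("weights incomplete for nucleus %s", nuc), call. = FALSE)
    f <- p$fourier[[nuc]]
    if (is.null(f) || length(f$phi) != 6L || length(f$psi) != 6L)
      stop(sprintf("fourier coefficients incomplete for nucleus %s", nuc),
           call. = FALSE)
  }
  if (!all(ANI_KINDS %in% names(p$delta_chi)))
    stop("delta_chi must cover backbone, OCN, OCO, NCN", call. = FALSE)
  if (!all(names(RING_DEFS) %in% names(p$ring_intensity)))
    stop("ring_intensity must cover PHE, TYR, HIS, TRP5, TRP6", call. = FALSE)
  cuts <- p$cutoffs
  if (any(unlist(cuts) <= 0))
    stop("all geometric cutoffs must be positive", call. = FALSE)
  invisible(p)
}

#' Write a parameter set to a YAML file
#'
#' @param params A `parameter_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  out <- unclass(params)
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf(paste0("<parameter_set> format v%d; %d random-coil entries, ",
                     "ring B = %g, cutoffs: contact %g A, hbond %g A, ",
                     "ani %g A, ring %g A\n"),
              x$format_version, length(x$random_coil) * length(NUCLEI),
              x$ring_scale, x$cutoffs$contact_radius,
              x$cutoffs$hbond_max_da_dist, x$cutoffs$ani_max_dist,
              x$cutoffs$ring_max_dist))
  invisible(x)
}

# Truncated Fourier series of the dihedral term for one nucleus:
# sum_{k=1..3} a_k cos(k phi) + b_k sin(k phi), plus the same in psi.
# Coefficient layout: c(a1, a2, a3, b1, b2, b3).  Absent angles (chain
# termini) contribute 0.  Vectorized over residues.
fourier_dihedral <- function(phi, psi, coef) {
  acc <- numeric(length(phi))
  for (ang_name in c("phi", "psi")) {
    ang <- if (ang_name == "phi") phi else psi
    cc <- coef[[ang_name]]
    rad <- ang / DEG
    term <- numeric(length(ang))
    for (k in 1:3)
      term <- term + cc[k] * cos(k * rad) + cc[k + 3] * sin(k * rad)
    term[is.na(ang)] <- 0
    acc <- acc + term
  }
  acc
}
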