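# Combine descriptors with a parameter set into per-nucleus predictions,
# fit descriptor weights from observed shifts, and score agreement.

#' Predict chemical shifts for a structure
#'
#' For every query nucleus the predicted shift is
#' `random_coil(res, nucleus) + sum_family w(nucleus, family) * descriptor`,
#' where the dihedral family's descriptor is the truncated phi/psi Fourier
#' series evaluated with the nucleus' coefficients.  Families whose
#' geometric prerequisites are absent (e.g. hydrogen bonds in a
#' hydrogen-free structure, phi at an N-terminus) contribute 0.
#'
#' @param structure A `protein_structure`.
#' @param selection Its `selection_set`; built (and proton-filtered) on
#'   demand when `NULL`.
#' @param params A `parameter_set`.
#' @param mode `"reference"`, `"batched"` or `"batched-unordered"`; both
#'   batched modes run the one-pass vectorized path, the latter with
#'   reversed accumulation order.
#' @return A `shift_table` data frame with columns `chain`, `res_seq`,
#'   `res_name`, `nucleus`, `shift_ppm` (plus `atom`), one row per
#'   (atom, nucleus) pair.
#' @export
predict_shifts <- function(structure, selection = NULL, params = default_params(),
                           mode = c("reference", "batched",
                                    "batched-unordered")) {
  mode <- match.arg(mode)
  if (is.null(selection))
    selection <- clear_protons(get_select(structure), structure)
  desc <- compute_descriptors(structure, selection, params, mode)
  build_shift_table(desc, params)
}

# Assemble predictions from a descriptor table.  Shared by prediction and
# fitting so both see exactly the same model structure.
build_shift_table <- function(desc, params) {
  n <- nrow(desc)
  shift <- numeric(n)
  keep <- rep(TRUE, n)
  for (nuc in unique(desc$nucleus)) {
    rows <- which(desc$nucleus == nuc)
    w <- params$weights[[nuc]]
    rc <- vapply(desc$res_name[rows], function(rn) {
      v <- params$random_coil[[rn]][[nuc]]
      if (is.null(v)) NA_real_ else v
    }, numeric(1), USE.NAMES = FALSE)
    miss <- is.na(rc)
    if (any(miss)) {
      warning(sprintf("no random-coil entry for %s; %d row(s) skipped",
                      paste(unique(desc$res_name[rows][miss]), collapse = ", "),
                      sum(miss)), call. = FALSE)
      keep[rows[miss]] <- FALSE
    }
    dih <- fourier_dihedral(desc$phi[rows], desc$psi[rows],
                            params$fourier[[nuc]])
    shift[rows] <- rc +
      w$contact * desc$contact[rows] +
      w$hbond * desc$hbond[rows] +
      w$ani * desc$ani[rows] +
      w$ring * desc$ring[rows] +
      w$dihedral * dih
  }
  out <- data.frame(
    chain = desc$chain, res_seq = desc$res_seq, res_name = desc$res_name,
    nucleus = desc$nucleus, shift_ppm = shift, atom = desc$atom,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$chain, out$res_seq,
                   match(out$nucleus, NUCLEI)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("shift_table", "data.frame")
  out
}

#' Root-mean-square and maximum error between two shift tables
#'
#' Matches rows on (chain, res_seq, nucleus) for the chosen nucleus class
#' and returns `sqrt(sum((P - O)^2) / n)` together with the maximum absolute
#' residual.
#'
#' @param predicted,observed `shift_table` data frames.
#' @param nucleus One of `"CA"`, `"CB"`, `"C"`, `"HN"`, `"N"`, `"HA"`, or
#'   `"all"` to pool every matched row.
#' @return List with `rmse`, `max_error` and `n`.
#' @export
rmse_shifts <- function(predicted, observed, nucleus = "all") {
  if (nucleus != "all") {
    predicted <- predicted[predicted$nucleus == nucleus, , drop = FALSE]
    observed <- observed[observed$nucleus == nucleus, , drop = FALSE]
  }
  key <- function(df) paste(df$chain, df$res_seq, df$nucleus, sep = "|")
  m <- match(key(predicted), key(observed))
  ok <- !is.na(m)
  if (!any(ok))
    stop("empty comparison: no matching (chain, res_seq, nucleus) rows",
         call. = FALSE)
  r <- predicted$shift_ppm[ok] - observed$shift_ppm[m[ok]]
  list(rmse = sqrt(sum(r * r) / length(r)), max_error = max(abs(r)),
       n = length(r))
}

#' Fit descriptor weights by per-nucleus least squares
#'
#' For each nucleus class, solves an ordinary least-squares problem for the
#' descriptor-family weights that minimize the squared deviation between
#' predicted and observed shifts, holding the random-coil baselines fixed
#' (set `fit_random_coil = TRUE` to free per-residue-type offsets).
#' Descriptor columns that are identically zero across the training data
#' (e.g. the hydrogen-bond column for hydrogen-free structures) are dropped
#' from the design and keep their base weight.
#'
#' @param training List of `list(structure = , observed = )` pairs; observed
#'   tables use the `shift_table` schema.
#' @param base Base `parameter_set`; supplies cutoffs, constants, Fourier
#'   coefficients and the random-coil table.
#' @param fit_random_coil Also fit per-residue-type additive offsets.
#' @param ridge Optional ridge penalty (default from `base$ridge`).
#' @param mode Descriptor execution mode used to build the design matrix.
#' @return The fitted `parameter_set`, with attributes `fit` (per-nucleus
#'   coefficient tables with standard errors) and `training_rmse`
#'   (per-nucleus RMSE of the fitted model on the training data).
#' @export
fit_parameters <- function(training, base = default_params(),
                           fit_random_coil = FALSE, ridge = NULL,
                           mode = "batched") {
  if (length(training) < 1L) stop("need at least one training pair",
                                  call. = FALSE)
  if (is.null(ridge)) ridge <- base$ridge
  desc_all <- NULL
  for (ti in seq_along(training)) {
    tr <- training[[ti]]
    sel <- clear_protons(get_select(tr$structure), tr$structure)
    d <- compute_descriptors(tr$structure, sel, base, mode)
    okey <- paste(tr$observed$chain, tr$observed$res_seq, tr$observed$nucleus,
                  sep = "|")
    m <- match(paste(d$chain, d$res_seq, d$nucleus, sep = "|"), okey)
    d$observed <- tr$observed$shift_ppm[m]
    desc_all <- rbind(desc_all, d[!is.na(m), , drop = FALSE])
  }
  if (is.null(desc_all) || nrow(desc_all) == 0L)
    stop("no observed rows match any computable descriptor row",
         call. = FALSE)

  fitted <- base
  fit_info <- list()
  training_rmse <- c()
  for (nuc in NUCLEI) {
    rows <- desc_all[desc_all$nucleus == nuc, , drop = FALSE]
    if (nrow(rows) == 0L) next
    rc <- vapply(rows$res_name,
                 function(rn) base$random_coil[[rn]][[nuc]] %||% NA_real_,
                 numeric(1), USE.NAMES = FALSE)
    rows <- rows[!is.na(rc), , drop = FALSE]
    rc <- rc[!is.na(rc)]
    dih <- fourier_dihedral(rows$phi, rows$psi, base$fourier[[nuc]])
    X <- cbind(contact = rows$contact, hbond = rows$hbond,
               ani = rows$ani, ring = rows$ring, dihedral = dih)
    active <- colSums(X != 0) > 0
    Xa <- X[, active, drop = FALSE]
    if (ncol(Xa) == 0L)
      stop(sprintf("under-determined fit for nucleus %s: no informative descriptor columns",
                   nuc), call. = FALSE)
    y <- rows$observed - rc
    df <- as.data.frame(Xa)
    if (fit_random_coil && length(unique(rows$res_name)) > 1L)
      df$res_name <- factor(rows$res_name)
    if (nrow(df) < ncol(Xa) + fit_random_coil * length(unique(rows$res_name)))
      stop(sprintf("under-determined fit for nucleus %s: %d rows, %d unknowns",
                   nuc, nrow(df), ncol(Xa)), call. = FALSE)
    fml <- if (fit_random_coil && !is.null(df$res_name))
      stats::as.formula(paste("y ~", paste(colnames(Xa), collapse = " + "),
                              "+ res_name"))
    else
      stats::as.formula(paste("y ~ 0 +", paste(colnames(Xa), collapse = " + ")))
    fit <- if (ridge > 0) {
      # closed-form ridge on the standardized design; OLS when ridge = 0
      XtX <- crossprod(Xa) + diag(ridge, ncol(Xa))
      beta <- solve(XtX, crossprod(Xa, y))
      list(coefficients = stats::setNames(as.numeric(beta), colnames(Xa)),
           lm = NULL)
    } else {
      lmfit <- stats::lm(fml, data = df)
      list(coefficients = stats::coef(lmfit), lm = lmfit)
    }
    co <- fit$coefficients
    w <- fitted$weights[[nuc]]
    for (fam in colnames(Xa))
      if (!is.na(co[[fam]])) w[[fam]] <- unname(co[[fam]])
    fitted$weights[[nuc]] <- w
    pred <- rc + as.numeric(X %*% unlist(w[colnames(X)]))
    if (fit_random_coil && !is.null(fit$lm))
      pred <- rc + stats::fitted(fit$lm)
    training_rmse[nuc] <- sqrt(mean((pred - rows$observed)^2))
    se <- if (!is.null(fit$lm)) {
      s <- tryCatch(suppressWarnings(summary(fit$lm))$coefficients,
                    error = function(e) NULL)
      if (is.null(s)) rep(NA_real_, length(co)) else s[names(co), "Std. Error"]
    } else rep(NA_real_, length(co))
    fit_info[[nuc]] <- data.frame(term = names(co),
                                  estimate = unname(unlist(co)),
                                  std_error = unname(se),
                                  stringsAsFactors = FALSE)
  }
  attr(fitted, "fit") <- fit_info
  attr(fitted, "training_rmse") <- training_rmse
  fitted
}
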