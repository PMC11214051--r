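#' Vectorize a symmetric RDM
#'
#' Extracts the strict lower triangle (excluding the diagonal) in a
#' fixed order: down the columns, i.e. (2,1), (3,1), ..., (n,1), (3,2),
#' ...  This is the canonical vectorization used everywhere in the
#' package; by symmetry it carries the same information as the upper
#' triangle.
#'
#' @param rdm square symmetric numeric matrix (diagonal may be NA)
#' @param tol symmetry tolerance
#' @return numeric vector of length n(n-1)/2
#' @export
vectorize_rdm <- function(rdm, tol = 1e-8) {
  m <- if (is.list(rdm) && !is.null(rdm$values)) rdm$values else rdm
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("RDM must be square")
  off <- which(lower.tri(m))
  asym <- max(abs(m[off] - t(m)[off]), na.rm = TRUE)
  if (is.finite(asym) && asym > tol)
    stop("RDM is asymmetric beyond tolerance (max deviation ",
         format(asym), ")")
  m[off]
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms all vectors (average ranks for ties), residualizes
#' the ranked `x` and `y` on the ranked covariates plus an intercept by
#' least squares, and returns the Pearson correlation of the residuals.
#' With no covariates this reduces to the ordinary Spearman rank
#' correlation.
#'
#' @param x,y numeric vectors
#' @param covariates list of numeric vectors (possibly empty)
#' @return partial rank correlation in [-1, 1]; `NA` when an input is
#'   constant after ranking or a covariate leaves (near-)zero residual
#'   variance
#' @export
spearman_partial <- function(x, y, covariates = list()) {
  n <- length(x)
  if (length(y) != n || any(vapply(covariates, length, 1L) != n))
    stop("all vectors must have equal length")
  if (n < 4 + length(covariates))
    stop("need at least ", 4 + length(covariates), " observations")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  if (!length(covariates)) return(cor(rx, ry))
  Z <- cbind(1, do.call(cbind, lapply(covariates, rank)))
  qz <- qr(Z)
  ex <- qr.resid(qz, rx)
  ey <- qr.resid(qz, ry)
  if (sd(ex) < 1e-10 * sd(rx) || sd(ey) < 1e-10 * sd(ry))
    return(NA_real_)
  cor(ex, ey)
}

#' Specification of a nested RSA model
#'
#' Model 0 partials out nothing; Model 1 partials the LTAS cosine RDM;
#' Model 2 additionally the acoustic principal-component RDMs; Model 3
#' additionally the behavioral RDMs of all other retained
#' characteristics.
#'
#' @param model_id one of "M0", "M1", "M2", "M3"
#' @param target_characteristic label of the target characteristic
#' @param covariate_names character vector naming the covariate RDMs
#' @return object of class `rsa_model_spec`
#' @export
rsa_model_spec <- function(model_id = c("M1", "M2", "M3", "M0"),
                           target_characteristic,
                           covariate_names = character(0)) {
  model_id <- match.arg(model_id)
  if (target_characteristic %in% covariate_names)
    stop("target characteristic cannot be among the covariates")
  structure(list(model_id = model_id,
                 target_characteristic = target_characteristic,
                 covariate_names = covariate_names),
            class = "rsa_model_spec")
}

#' Time-resolved partial Spearman correlation for one participant
#'
#' Correlates the vectorized neural RDM at every time point with the
#' vectorized target RDM, partialling out the vectorized covariate RDMs
#' (time-invariant; pre-ranked once).
#'
#' @param neural a `neural_rdm_series`
#' @param target target RDM (matrix, `behavioral_rdm`, or vector from
#'   [vectorize_rdm()])
#' @param covariates list of covariate RDMs (same item set and order)
#' @param spec optional `rsa_model_spec` recorded with the result
#' @return object of class `rsa_timecourse`: `rho` (numeric per time
#'   point), `times`, `spec`
#' @export
run_model <- function(neural, target, covariates = list(), spec = NULL) {
  n_stim <- length(neural$stimulus_ids)
  check_items <- function(obj, what) {
    m <- if (is.list(obj) && !is.null(obj$values)) obj$values else obj
    if (is.matrix(m)) {
      if (nrow(m) != n_stim)
        stop(what, " has ", nrow(m), " items; neural series has ", n_stim)
      rn <- rownames(m)
      if (!is.null(rn) && !identical(rn, neural$stimulus_ids))
        stop(what, " item ordering does not match the neural series")
      vectorize_rdm(m)
    } else {
      if (length(m) != n_stim * (n_stim - 1) / 2)
        stop(what, " vector has wrong length")
      as.numeric(m)
    }
  }
  tv <- check_items(target, "target RDM")
  cvs <- lapply(seq_along(covariates), function(i)
    check_items(covariates[[i]], paste0("covariate RDM ", i)))
  n_t <- length(neural$times)
  lower <- which(lower.tri(matrix(0, n_stim, n_stim)))
  rho <- numeric(n_t)
  if (length(cvs)) {
    Z <- cbind(1, do.call(cbind, lapply(cvs, rank)))
    qz <- qr(Z)
    ry <- rank(tv)
    ey <- qr.resid(qz, ry)
    sy <- sd(ey)
    if (sy < 1e-10 * max(sd(ry), 1)) {
      rho[] <- NA_real_
    } else {
      for (t in seq_len(n_t)) {
        nv <- neural$values[t, , ][lower]
        rxn <- rank(nv)
        if (sd(rxn) == 0) { rho[t] <- NA_real_; next }
        ex <- qr.resid(qz, rxn)
        if (sd(ex) < 1e-10 * sd(rxn)) { rho[t] <- NA_real_; next }
        rho[t] <- cor(ex, ey)
      }
    }
  } else {
    ry <- rank(tv)
    if (sd(ry) == 0) rho[] <- NA_real_
    else for (t in seq_len(n_t)) {
      nv <- neural$values[t, , ][lower]
      rxn <- rank(nv)
      rho[t] <- if (sd(rxn) == 0) NA_real_ else cor(rxn, ry)
    }
  }
  structure(list(rho = rho, times = neural$times, spec = spec,
                 participant_id = neural$participant_id),
            class = "rsa_timecourse")
}

#' Run the nested model family for all participants and characteristics
#'
#' For every participant, retained characteristic and requested model,
#' computes the time-resolved partial Spearman correlation between the
#' neural RDM series and the characteristic's behavioral RDM.
#' Covariates: M0 none; M1 the LTAS RDM; M2 the LTAS RDM plus the
#' acoustic principal-component RDMs; M3 additionally the behavioral
#' RDMs of all other retained characteristics.
#'
#' @param neural_list list of `neural_rdm_series`, one per participant
#' @param behavioral_rdms named list of behavioral RDM matrices (one
#'   per retained characteristic)
#' @param acoustic_rdms an `acoustic_rdm_set`
#' @param models character subset of c("M0", "M1", "M2", "M3")
#' @return long data.frame: `participant`, `characteristic`, `model`,
#'   `time_ms`, `rho`
#' @export
run_all_models <- function(neural_list, behavioral_rdms, acoustic_rdms,
                           models = c("M1", "M2", "M3")) {
  if (!length(neural_list)) stop("need at least one participant")
  models <- match.arg(models, c("M0", "M1", "M2", "M3"),
                      several.ok = TRUE)
  chars <- names(behavioral_rdms)
  acov <- c(list(LTAS = acoustic_rdms$ltas_rdm), acoustic_rdms$pc_rdms)
  out <- vector("list", 0)
  for (pi in seq_along(neural_list)) {
    neural <- neural_list[[pi]]
    for (ch in chars) {
      for (mid in models) {
        covs <- switch(mid,
          M0 = list(),
          M1 = acov["LTAS"],
          M2 = acov,
          M3 = c(acov, behavioral_rdms[setdiff(chars, ch)]))
        spec <- rsa_model_spec(mid, ch, names(covs) %||% character(0))
        tc <- run_model(neural, behavioral_rdms[[ch]], covs, spec)
        out[[length(out) + 1L]] <- data.frame(
          participant = neural$participant_id, characteristic = ch,
          model = mid, time_ms = tc$times, rho = tc$rho,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Participant x time matrix for one characteristic and model
#'
#' Reshapes the long time-course table from [run_all_models()] for
#' group-level inference.
#'
#' @param timecourses long data.frame from [run_all_models()]
#' @param characteristic,model selection
#' @return numeric matrix participants x time, with the time axis in
#'   `attr(, "times")`
#' @export
timecourse_matrix <- function(timecourses, characteristic, model) {
  sub <- timecourses[timecourses$characteristic == characteristic &
                       timecourses$model == model, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for ", characteristic, " / ", model)
  times <- sort(unique(sub$time_ms))
  parts <- unique(sub$participant)
  m <- matrix(NA_real_, length(parts), length(times),
              dimnames = list(parts, NULL))
  m[cbind(match(sub$participant, parts), match(sub$time_ms, times))] <-
    sub$rho
  attr(m, "times") <- times
  m
}
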