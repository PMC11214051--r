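#' Person characteristics modelled by the pipeline
#'
#' The eight characteristics carried by the latent trait space, plus
#' the ninth rating scale (`sexual_orientation`) that is collected but
#' typically fails the inter-rater agreement screen.
#' @export
voice_characteristics <- function(include_screened_out = FALSE) {
  base <- c("gender", "age", "health", "attractiveness", "dominance",
            "trustworthiness", "educatedness", "professionalism")
  if (include_screened_out) c(base, "sexual_orientation") else base
}

#' Generate a latent person-characteristic space
#'
#' Speakers receive standardized scores on `n_latent` independent
#' latent trait dimensions.  The eight person characteristics are
#' linear combinations of the latents (via `loading_spec`, n_latent x 8)
#' plus per-characteristic unique residuals, so the implied
#' characteristic correlation matrix is available in closed form:
#' `cov2cor(t(L) %*% L + diag(uniqueness^2))`.  A loading structure
#' with shared latents across valenced traits reproduces the high
#' rating intercorrelations ("halo"-like structure) seen in person
#' perception.
#'
#' @param n_speakers number of speakers
#' @param n_latent number of latent trait dimensions
#' @param loading_spec numeric matrix n_latent x 8 of loadings (columns
#'   may be named with the characteristics); default: two latents, one
#'   shared by the valenced/trait characteristics and one carrying the
#'   physical characteristics
#' @param uniqueness numeric vector of per-characteristic residual SDs
#'   (length 8, recycled)
#' @param seed integer seed
#' @return object of class `latent_person_space`: `latent_scores`
#'   (speakers x n_latent, exactly standardized), `loading_matrix`,
#'   `uniqueness`, `implied_correlation`
#' @export
generate_latent_space <- function(n_speakers = 32, n_latent = 2,
                                  loading_spec = NULL,
                                  uniqueness = 0.4, seed = 1) {
  chars <- voice_characteristics()
  if (is.null(loading_spec)) {
    loading_spec <- default_loading_spec(n_latent)
  }
  loading_spec <- as.matrix(loading_spec)
  if (ncol(loading_spec) != length(chars))
    stop("`loading_spec` must have ", length(chars), " columns ",
         "(one per characteristic)")
  if (nrow(loading_spec) != n_latent)
    stop("`loading_spec` must have n_latent = ", n_latent, " rows")
  if (!all(is.finite(loading_spec)))
    stop("`loading_spec` contains non-finite values")
  if (n_latent < 1) stop("`n_latent` must be >= 1")
  uniqueness <- rep_len(as.numeric(uniqueness), length(chars))
  if (any(uniqueness < 0)) stop("`uniqueness` must be non-negative")
  colnames(loading_spec) <- chars
  sigma <- crossprod(loading_spec) + diag(uniqueness^2)
  tot <- diag(sigma)
  if (any(tot <= 0))
    stop("loading_spec implies zero total variance for: ",
         paste(chars[tot <= 0], collapse = ", "))
  implied <- stats::cov2cor(sigma)
  ev <- eigen(implied, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("loading_spec implies a non-positive-semi-definite ",
         "characteristic correlation matrix")
  scores <- with_seed(seed, matrix(rnorm(n_speakers * n_latent),
                                   n_speakers, n_latent))
  # exact standardization: zero mean, unit variance per dimension
  scores <- scale(scores)
  attr(scores, "scaled:center") <- NULL
  attr(scores, "scaled:scale") <- NULL
  colnames(scores) <- paste0("latent", seq_len(n_latent))
  structure(list(latent_scores = scores, loading_matrix = loading_spec,
                 uniqueness = uniqueness, implied_correlation = implied,
                 seed = seed),
            class = "latent_person_space")
}

# Default two-latent structure: latent 1 carries the valenced "trait"
# characteristics (health, attractiveness, dominance, trustworthiness,
# educatedness, professionalism), latent 2 the physical ones (gender,
# age) with mild cross-loadings.
default_loading_spec <- function(n_latent = 2) {
  chars <- voice_characteristics()
  L <- matrix(0, n_latent, length(chars), dimnames = list(NULL, chars))
  trait <- c("health", "attractiveness", "dominance", "trustworthiness",
             "educatedness", "professionalism")
  phys <- c("gender", "age")
  L[1L, trait] <- 0.85
  if (n_latent >= 2) {
    L[2L, phys] <- 0.9
    L[2L, c("attractiveness", "health")] <- 0.25
  } else {
    L[1L, phys] <- 0.6
  }
  L
}

# Per-stimulus characteristic values on the latent z scale: speaker
# latent projection + per-characteristic speaker residual + independent
# stimulus-level jitter (the same speaker's vowels share the speaker
# part but not the jitter).
characteristic_values <- function(space, stimuli,
                                  stimulus_jitter_sd = 0.3, seed = 1) {
  chars <- colnames(space$loading_matrix)
  sp <- unique(stimuli$speaker_id)
  if (nrow(space$latent_scores) != length(sp))
    stop("latent space has ", nrow(space$latent_scores),
         " speakers but stimulus set has ", length(sp))
  with_seed(seed, {
    resid <- matrix(rnorm(length(sp) * length(chars)), length(sp),
                    dimnames = list(sp, chars))
    speaker_vals <- space$latent_scores %*% space$loading_matrix +
      resid * rep(space$uniqueness, each = length(sp))
    rownames(speaker_vals) <- sp
    jit <- matrix(rnorm(nrow(stimuli) * length(chars), sd = stimulus_jitter_sd),
                  nrow(stimuli), length(chars))
    vals <- speaker_vals[stimuli$speaker_id, , drop = FALSE] + jit
    rownames(vals) <- stimuli$stimulus_id
    vals
  })
}

#' Generate integer ratings from a latent person space
#'
#' Every rater judges every stimulus on the eight latent-driven
#' characteristic scales plus, optionally, a pure-noise
#' `sexual_orientation` scale (emulating a scale on which raters do not
#' agree).  Latent-driven characteristic values (z scale) are mapped
#' affinely to the 1-9 scale (mean 5, SD 1.5), rater noise is added,
#' and responses are rounded and clipped to [1, 9].
#'
#' @param space a `latent_person_space`
#' @param stimuli stimulus set
#' @param n_raters number of raters (>= 2)
#' @param rater_noise_sd SD of per-response rater noise, in scale units
#' @param stimulus_jitter_sd SD of stimulus-level (within-speaker)
#'   jitter on the latent z scale
#' @param include_noise_scale add the pure-noise ninth scale?
#' @param seed integer seed
#' @return object of class `rating_table`: long data.frame with columns
#'   `rater_id`, `stimulus_id`, `characteristic`, `rating`
#' @export
generate_ratings <- function(space, stimuli, n_raters = 20,
                             rater_noise_sd = 1.5,
                             stimulus_jitter_sd = 0.3,
                             include_noise_scale = TRUE, seed = 1) {
  if (n_raters < 2) stop("`n_raters` must be >= 2")
  vals <- characteristic_values(space, stimuli, stimulus_jitter_sd,
                                seed = derive_seed(seed, 1L))
  if (include_noise_scale)
    vals <- cbind(vals, sexual_orientation = 0)
  chars <- colnames(vals)
  n_stim <- nrow(vals)
  with_seed(derive_seed(seed, 2L), {
    out <- expand.grid(characteristic = chars,
                       stimulus_id = rownames(vals),
                       rater_id = sprintf("R%03d", seq_len(n_raters)),
                       stringsAsFactors = FALSE)[, 3:1]
    true_scale <- 5 + 1.5 * as.vector(t(vals))  # characteristic-fastest
    noise <- rnorm(nrow(out), sd = rater_noise_sd)
    out$rating <- as.integer(pmin(9, pmax(1, round(
      rep_len(true_scale, nrow(out)) + noise))))
    structure(out, class = c("rating_table", "data.frame"),
              characteristics = chars)
  })
}
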