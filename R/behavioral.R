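#' Screen raters for uninformative response patterns
#'
#' Per (rater, characteristic), computes the fraction of trials on
#' which the rater gave their modal response; pairs with a fraction
#' strictly greater than `max_same_fraction` are excluded.
#'
#' @param ratings a `rating_table` (long data.frame: `rater_id`,
#'   `stimulus_id`, `characteristic`, `rating`)
#' @param max_same_fraction exclusion threshold (strict inequality)
#' @return object of class `rater_screen_report`: `excluded`
#'   (data.frame rater_id/characteristic), `max_same_fraction` (per
#'   pair), `threshold`
#' @export
screen_raters <- function(ratings, max_same_fraction = 0.8) {
  validate_rating_table(ratings)
  key <- interaction(ratings$rater_id, ratings$characteristic, drop = TRUE)
  frac <- tapply(ratings$rating, key, function(r)
    max(table(r)) / length(r))
  parts <- do.call(rbind, strsplit(names(frac), ".", fixed = TRUE))
  tab <- data.frame(rater_id = parts[, 1], characteristic = parts[, 2],
                    max_same_fraction = as.numeric(frac),
                    stringsAsFactors = FALSE)
  excluded <- tab[tab$max_same_fraction > max_same_fraction,
                  c("rater_id", "characteristic")]
  rownames(excluded) <- NULL
  structure(list(excluded = excluded, max_same_fraction = tab,
                 threshold = max_same_fraction),
            class = "rater_screen_report")
}

validate_rating_table <- function(ratings) {
  need <- c("rater_id", "stimulus_id", "characteristic", "rating")
  miss <- setdiff(need, names(ratings))
  if (length(miss))
    stop("rating table lacks column(s): ", paste(miss, collapse = ", "))
  r <- ratings$rating
  if (any(!is.na(r) & (r != round(r) | r < 1 | r > 9)))
    stop("ratings must be integers in [1, 9]")
  invisible(ratings)
}

#' Intraclass correlation ICC(2,k)
#'
#' Two-way random-effects intraclass correlation for the reliability of
#' the mean of k raters (Shrout-Fleiss ICC(2,k)), computed from the
#' two-way ANOVA mean squares:
#' `(MS_items - MS_error) / (MS_items + (MS_raters - MS_error) / n_items)`.
#'
#' @param x numeric matrix, items (stimuli) x raters, no missing cells
#' @return the ICC(2,k) value; `NA` with attribute `undefined = TRUE`
#'   when the denominator is zero (fully degenerate table)
#' @export
icc2k <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need >= 2 items and >= 2 raters")
  if (anyNA(x)) stop("missing cells; apply listwise deletion first")
  gm <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ss_items <- k * sum((rm_ - gm)^2)
  ss_raters <- n * sum((cm - gm)^2)
  ss_total <- sum((x - gm)^2)
  ss_error <- ss_total - ss_items - ss_raters
  ms_items <- ss_items / (n - 1)
  ms_raters <- ss_raters / (k - 1)
  ms_error <- ss_error / ((n - 1) * (k - 1))
  den <- ms_items + (ms_raters - ms_error) / n
  if (abs(den) < 1e-300) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  (ms_items - ms_error) / den
}

# ICC(2,k) per characteristic after screening, with listwise deletion
# of raters that miss any stimulus for that scale.
icc_by_characteristic <- function(ratings, screen = NULL) {
  chars <- unique(ratings$characteristic)
  out <- setNames(numeric(length(chars)), chars)
  for (ch in chars) {
    sub <- ratings[ratings$characteristic == ch, , drop = FALSE]
    if (!is.null(screen)) {
      drop <- screen$excluded$rater_id[screen$excluded$characteristic == ch]
      sub <- sub[!sub$rater_id %in% drop, , drop = FALSE]
    }
    m <- rating_matrix(sub)
    out[ch] <- if (ncol(m) >= 2) icc2k(m) else NA_real_
  }
  out
}

# stimulus x rater matrix for one characteristic; raters with missing
# stimuli are dropped (listwise).
rating_matrix <- function(sub) {
  stims <- sort(unique(sub$stimulus_id))
  raters <- sort(unique(sub$rater_id))
  m <- matrix(NA_real_, length(stims), length(raters),
              dimnames = list(stims, raters))
  m[cbind(match(sub$stimulus_id, stims), match(sub$rater_id, raters))] <-
    sub$rating
  m[, colSums(is.na(m)) == 0, drop = FALSE]
}

#' Mean ratings per stimulus and characteristic
#'
#' Averages ratings over the raters retained per characteristic
#' (screening exclusions are scale-specific) and drops characteristics
#' whose inter-rater agreement falls below `min_icc` — emulating the
#' exclusion of a scale on which raters do not agree.
#'
#' @param ratings a `rating_table`
#' @param screen a `rater_screen_report` from [screen_raters()]
#' @param min_icc minimum ICC(2,k) for a characteristic to be retained
#' @return object of class `mean_ratings`: `values` (stimulus x
#'   characteristic matrix), `n_raters_used`, `icc2k`,
#'   `dropped_characteristics`
#' @export
mean_ratings <- function(ratings, screen = screen_raters(ratings),
                         min_icc = 0.5) {
  validate_rating_table(ratings)
  chars <- unique(ratings$characteristic)
  icc <- icc_by_characteristic(ratings, screen)
  # drop scales with poor agreement, and scales where screening left no
  # raters (ICC undefined on an empty or single-rater table)
  no_raters <- vapply(chars, function(ch) {
    excl <- screen$excluded$rater_id[screen$excluded$characteristic == ch]
    length(setdiff(unique(ratings$rater_id[ratings$characteristic == ch]),
                   excl)) == 0
  }, logical(1))
  drop_chars <- chars[(!is.na(icc) & icc < min_icc) | no_raters]
  keep_chars <- setdiff(chars, drop_chars)
  stims <- sort(unique(ratings$stimulus_id))
  vals <- matrix(NA_real_, length(stims), length(keep_chars),
                 dimnames = list(stims, keep_chars))
  n_used <- setNames(integer(length(keep_chars)), keep_chars)
  for (ch in keep_chars) {
    sub <- ratings[ratings$characteristic == ch, , drop = FALSE]
    excl <- screen$excluded$rater_id[screen$excluded$characteristic == ch]
    sub <- sub[!sub$rater_id %in% excl, , drop = FALSE]
    if (!nrow(sub))
      stop("no raters retained for characteristic ", ch)
    mns <- tapply(sub$rating, sub$stimulus_id, mean)
    vals[names(mns), ch] <- mns
    n_used[ch] <- length(unique(sub$rater_id))
  }
  structure(list(values = vals, n_raters_used = n_used, icc2k = icc,
                 dropped_characteristics = drop_chars),
            class = "mean_ratings")
}

#' Spearman correlations between characteristics
#'
#' Pairwise Spearman rank correlations (average ranks for ties) of the
#' mean ratings over stimuli.
#'
#' @param means a `mean_ratings` object (or a stimulus x characteristic
#'   matrix)
#' @return symmetric correlation matrix with unit diagonal; entries for
#'   constant columns are `NA`
#' @export
characteristic_correlations <- function(means) {
  v <- if (inherits(means, "mean_ratings")) means$values else as.matrix(means)
  if (nrow(v) < 3) stop("need >= 3 stimuli")
  const <- apply(v, 2, function(x) sd(x) == 0)
  out <- suppressWarnings(cor(v, method = "spearman"))
  out[const, ] <- NA_real_
  out[, const] <- NA_real_
  diag(out) <- 1
  out
}

#' Behavioral RDM from mean ratings
#'
#' The dissimilarity of two stimuli on one characteristic is the
#' absolute difference of their mean ratings.
#'
#' @param means a `mean_ratings` object
#' @param characteristic retained characteristic label
#' @return object of class `behavioral_rdm`: `values` (stimulus x
#'   stimulus), `characteristic`
#' @export
rating_rdm <- function(means, characteristic) {
  if (!characteristic %in% colnames(means$values))
    stop("characteristic ", characteristic,
         " is not among the retained characteristics")
  m <- means$values[, characteristic]
  values <- abs(outer(m, m, "-"))
  structure(list(values = values, characteristic = characteristic),
            class = "behavioral_rdm")
}
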