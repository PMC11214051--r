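#' Standard 32-channel EEG montage
#'
#' Idealized unit-sphere positions for a 32-channel 10-20 cap (the
#' layout includes the temporal electrodes Tp9 and Tp10 used as the
#' linked-mastoid-like reference).  Positions are given in head
#' coordinates with x to the right, y to the front and z up, derived
#' from inclination (angle from the vertex Cz) and azimuth (angle from
#' the front midline, positive to the right).
#'
#' @param labels optional character vector of channel labels to select
#'   (in the requested order).  Default: all 32 channels.
#' @return a data.frame with columns `label`, `x`, `y`, `z` (unit
#'   vectors).
#' @export
standard_montage <- function(labels = NULL) {
  tab <- list(
    # label       incl  azim
    c("Fp1",  72, -18), c("Fp2",  72,  18),
    c("F7",   72, -54), c("F3",   54, -30), c("Fz",   36,   0),
    c("F4",   54,  30), c("F8",   72,  54),
    c("FC5",  54, -65), c("FC1",  36, -45), c("FC2",  36,  45), c("FC6",  54,  65),
    c("T7",   72, -90), c("C3",   36, -90), c("Cz",    0,   0), c("C4",   36,  90),
    c("T8",   72,  90),
    c("TP9",  99, -100), c("CP5",  54, -115), c("CP1",  36, -135),
    c("CP2",  36, 135), c("CP6",  54, 115), c("TP10", 99, 100),
    c("P7",   72, -126), c("P3",   54, -150), c("Pz",   36, 180),
    c("P4",   54, 150), c("P8",   72, 126),
    c("PO9",  99, -140), c("O1",   72, -162), c("Oz",   72, 180),
    c("O2",   72, 162), c("PO10", 99, 140)
  )
  lab <- vapply(tab, `[`, character(1), 1L)
  incl <- as.numeric(vapply(tab, `[`, character(1), 2L)) * pi / 180
  azim <- as.numeric(vapply(tab, `[`, character(1), 3L)) * pi / 180
  pos <- data.frame(
    label = lab,
    x = sin(incl) * sin(azim),
    y = sin(incl) * cos(azim),
    z = cos(incl),
    stringsAsFactors = FALSE
  )
  if (!is.null(labels)) {
    idx <- match(labels, pos$label)
    if (anyNA(idx))
      stop("unknown channel label(s): ",
           paste(labels[is.na(idx)], collapse = ", "))
    pos <- pos[idx, , drop = FALSE]
    rownames(pos) <- NULL
  }
  pos
}
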