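#' Construct a TMT study design
#'
#' A study design maps the 12 reporter channels of one TMT plex onto the
#' differentiation time course: days 0, 2 and 6, with four biological
#' replicates per day. Each plex corresponds to one protease experiment
#' (trypsin/lys-C or chymotrypsin).
#'
#' @param plex_id Single string identifying the plex.
#' @param protease One of `"trypsin_lysc"` or `"chymotrypsin"`.
#' @param channels Character vector of 12 channel labels, in plex order.
#'   Defaults to TMTpro-style labels `126, 127N, ..., 131C`.
#' @param days,replicates Integer vectors (length 12, aligned with
#'   `channels`) giving the day (0/2/6) and replicate (1-4) of each channel.
#'   Defaults assign channels in day-major order.
#'
#' @return A tibble of class `kme_design` with columns `plex_id`, `protease`,
#'   `channel`, `day`, `replicate` and `sample` (the resolved sample label
#'   `d<day>_r<rep>`).
#' @examples
#' design <- study_design("plex1", "trypsin_lysc")
#' design
#' @export
study_design <- function(plex_id, protease = c("trypsin_lysc", "chymotrypsin"),
                         channels = NULL, days = NULL, replicates = NULL) {
  protease <- match.arg(protease)
  if (is.null(channels)) {
    channels <- c(
      "126", "127N", "127C", "128N", "128C", "129N",
      "129C", "130N", "130C", "131N", "131C", "132N"
    )
  }
  if (length(channels) != 12 || anyDuplicated(channels)) {
    abort("A TMT plex design requires exactly 12 distinct channel labels.")
  }
  if (is.null(days)) days <- rep(c(0L, 2L, 6L), each = 4L)
  if (is.null(replicates)) replicates <- rep(1:4, times = 3L)
  days <- as.integer(days)
  replicates <- as.integer(replicates)
  if (!setequal(unique(days), c(0L, 2L, 6L))) {
    abort("Design days must be exactly {0, 2, 6}.")
  }
  key <- paste(days, replicates)
  if (length(key) != 12 || anyDuplicated(key) ||
      !all(replicates %in% 1:4)) {
    abort("Each (day, replicate) pair must occur exactly once (n = 4 per day).")
  }
  out <- tibble::tibble(
    plex_id = plex_id,
    protease = protease,
    channel = as.character(channels),
    day = days,
    replicate = replicates,
    sample = sample_label(days, replicates)
  )
  class(out) <- c("kme_design", class(out))
  out
}

#' Default two-plex design of the differentiation study
#'
#' One 12-plex per protease (trypsin/lys-C and chymotrypsin), each covering
#' days 0/2/6 with four replicates.
#'
#' @return A named list of two `kme_design` tibbles.
#' @export
default_study_designs <- function() {
  list(
    trypsin_lysc = study_design("plex_tryp", "trypsin_lysc"),
    chymotrypsin = study_design("plex_chymo", "chymotrypsin")
  )
}

design_samples <- function(design) design$sample

assert_design <- function(design) {
  if (!inherits(design, "kme_design")) {
    abort("`design` must be created with `study_design()`.")
  }
  invisible(design)
}
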