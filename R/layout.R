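#' Circumferential headband electrode layout
#'
#' The rapid-response headband carries ten electrodes: 1-5 over the left
#' lateral chain and 6-10 over the right, numbered anterior to posterior
#' (1 and 6 near the frontal pole, 5 and 10 near the occiput).  The eight
#' derivations of the longitudinal bipolar montage subtract each electrode
#' from its posterior neighbour within a chain, approximating the lateral
#' chains of the 10-20 system (Fp1-F7 ... T5-O1 on the left and Fp2-F8 ...
#' T6-O2 on the right).
#'
#' @param labels Character vector of 10 electrode names, anterior to
#'   posterior, left chain (5) then right chain (5).
#'
#' @return An object of class `electrode_layout`: a list with `labels`
#'   (length 10) and `pairs`, a tibble of 8 rows with columns `anterior`,
#'   `posterior` and `name` (`"anterior-posterior"`).
#' @export
#' @examples
#' headband_layout()
headband_layout <- function(labels = paste0("E", 1:10)) {
  if (length(labels) != 10L || anyDuplicated(labels)) {
    abort("A headband layout needs exactly 10 distinct electrode labels.",
          class = "szburden_error_input")
  }
  left <- labels[1:5]
  right <- labels[6:10]
  pairs <- tibble::tibble(
    anterior  = c(left[1:4], right[1:4]),
    posterior = c(left[2:5], right[2:5])
  )
  pairs$name <- paste0(pairs$anterior, "-", pairs$posterior)
  structure(list(labels = labels, pairs = pairs), class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat("<electrode_layout> 10 electrodes, 8 bipolar derivations\n")
  cat("left chain :", paste(x$labels[1:5], collapse = " -> "), "\n")
  cat("right chain:", paste(x$labels[6:10], collapse = " -> "), "\n")
  invisible(x)
}

#' Derive the 8-channel longitudinal bipolar montage
#'
#' Re-references a 10-channel referential record to the longitudinal bipolar
#' montage: output channel *i* is the anterior electrode of pair *i* minus
#' its posterior neighbour.  The operation is linear, so common-mode signals
#' (reference drift, DC offsets shared across electrodes) cancel exactly.
#'
#' @param record An [eeg_record()] whose channels are the 10 referential
#'   electrode signals named as in `layout$labels`.
#' @param layout An [headband_layout()] object.
#'
#' @return An [eeg_record()] with 8 bipolar channels named
#'   `"anterior-posterior"`, same rate and duration.
#' @export
#' @examples
#' lay <- headband_layout()
#' x <- matrix(rnorm(10 * 250), nrow = 10, dimnames = list(lay$labels))
#' build_bipolar_montage(eeg_record(x, 250), lay)
build_bipolar_montage <- function(record, layout) {
  assert_eeg_record(record)
  if (!inherits(layout, "electrode_layout")) {
    abort("`layout` must be an <electrode_layout>.", class = "szburden_error_input")
  }
  missing <- setdiff(layout$labels, record$channel_names)
  if (length(missing) > 0L) {
    abort(
      paste0("Record is missing electrode channel(s): ",
             paste(missing, collapse = ", ")),
      class = "szburden_error_channel_mismatch"
    )
  }
  out <- record$samples[layout$pairs$anterior, , drop = FALSE] -
    record$samples[layout$pairs$posterior, , drop = FALSE]
  rownames(out) <- layout$pairs$name
  eeg_record(out, rate = record$rate, channel_names = layout$pairs$name,
             start_time = record$start_time)
}
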