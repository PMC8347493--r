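#' Camera calibration tables
#'
#' Different fundus camera models respond differently to the same tissue;
#' a per-channel affine correction (gain and offset per camera model) brings
#' them to an equivalent response before colorimetry. The identity
#' calibration leaves every channel untouched, and because the haemoglobin
#' ratio (R-G)/R is invariant to a common channel gain, calibration only
#' matters when gains differ between channels or offsets are nonzero.
#'
#' @param table A data frame with columns `camera_id`, `channel`
#'   (`"red"|"green"|"blue"`), `gain` (> 0) and `offset`. Missing
#'   camera/channel combinations default to the identity.
#' @return An object of class `camera_calibration` (a tibble).
#' @export
camera_calibration <- function(table = NULL) {
  if (is.null(table)) {
    table <- tibble::tibble(camera_id = character(), channel = character(),
                            gain = numeric(), offset = numeric())
  }
  table <- tibble::as_tibble(table)
  need <- c("camera_id", "channel", "gain", "offset")
  if (!all(need %in% names(table))) {
    stop("calibration table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(table$gain <= 0)) stop("calibration gains must be > 0", call. = FALSE)
  bad <- setdiff(unique(table$channel), c("red", "green", "blue"))
  if (length(bad)) stop("unknown channels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  class(table) <- c("camera_calibration", class(table))
  table
}

#' Read a calibration table from YAML
#'
#' Expected layout: a top-level `cameras` mapping of camera_id to channel
#' entries, each with `gain` and `offset`, e.g.
#' ```yaml
#' cameras:
#'   nidek-afc210:
#'     red:   {gain: 1.02, offset: 0}
#'     green: {gain: 0.98, offset: 1.5}
#' ```
#'
#' @param path Path to a YAML file.
#' @return A [camera_calibration()].
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  cams <- y$cameras %||% list()
  rows <- purrr::imap(cams, function(chs, cam) {
    purrr::imap(chs, function(v, ch) {
      tibble::tibble(camera_id = cam, channel = ch,
                     gain = as.numeric(v$gain %||% 1),
                     offset = as.numeric(v$offset %||% 0))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  camera_calibration(rows)
}

#' Apply a camera calibration to an image
#'
#' Channel-wise affine transform `gain * value + offset`, clamped below at
#' zero (negative sensor values are not meaningful). Cameras absent from the
#' table are passed through unchanged when `fallback_identity = TRUE`
#' (the default is strict: an unknown camera is an error).
#'
#' @param image A [fundus_image()].
#' @param calib A [camera_calibration()], or `NULL` for identity.
#' @param fallback_identity If `TRUE`, a camera_id missing from the table
#'   gets the identity calibration instead of an error.
#' @return A calibrated `fundus_image`.
#' @export
apply_calibration <- function(image, calib = NULL, fallback_identity = FALSE) {
  stopifnot(inherits(image, "fundus_image"))
  if (is.null(calib) || nrow(calib) == 0) return(image)
  rows <- calib[calib$camera_id == image$camera_id, , drop = FALSE]
  if (nrow(rows) == 0) {
    if (fallback_identity) return(image)
    stop("camera_id '", image$camera_id, "' not present in calibration table ",
         "(set fallback_identity = TRUE to pass through)", call. = FALSE)
  }
  out <- image
  for (i in seq_len(nrow(rows))) {
    ch <- rows$channel[i]
    out[[ch]] <- pmax(rows$gain[i] * out[[ch]] + rows$offset[i], 0)
  }
  out
}
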