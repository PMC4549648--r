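# ChannelStack: one fluorescence channel as a T x H x W intensity stack with
# physical metadata. Lightweight S3, in the style of simple list-based
# containers (data stays a plain array so downstream math is direct).

#' Create a fluorescence channel stack
#'
#' @param data numeric `T x H x W` array (or `H x W` matrix, promoted to one
#'   frame) of nonnegative intensities.
#' @param role one of `"donor"`, `"raw_acceptor"`, `"corrected_fret"`,
#'   `"control_donor_only"`, `"control_acceptor_only"`.
#' @param pixel_size pixel size, micrometers per pixel.
#' @param frame_interval frame interval, seconds.
#' @param bit_depth nominal acquisition bit depth (16 for the sCMOS dialect
#'   modeled here); corrected stacks keep real values.
#' @return an object of class `channel_stack`.
#' @export
channel_stack <- function(data,
                          role = c("donor", "raw_acceptor", "corrected_fret",
                                   "control_donor_only", "control_acceptor_only"),
                          pixel_size, frame_interval, bit_depth = 16L) {
  role <- match.arg(role)
  if (is.matrix(data)) dim(data) <- c(1L, nrow(data), ncol(data))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[1] < 1L) stop("channel stack needs T >= 1 frames")
  if (any(!is.finite(data))) stop("channel stack intensities must be finite")
  if (min(data) < 0) stop("channel stack intensities must be nonnegative")
  stopifnot(is.numeric(pixel_size), pixel_size > 0,
            is.numeric(frame_interval), frame_interval > 0)
  structure(
    list(data = data, role = role, pixel_size = pixel_size,
         frame_interval = frame_interval, bit_depth = as.integer(bit_depth)),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<channel_stack> role=%s  %d frames x %d x %d px  (%.3g um/px, %.3g s/frame)\n",
    x$role, d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[1]

times_of <- function(stack) (seq_len(n_frames(stack)) - 1) * stack$frame_interval

stack_congruent <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(a$frame_interval, b$frame_interval))
}

# replace intensities, keeping metadata; role may be updated
restack <- function(stack, data, role = stack$role) {
  s <- stack
  s$data <- data
  s$role <- role
  s
}

#' Read a channel stack from a multi-page TIFF
#'
#' @param path TIFF path (as written by [write_tiff_stack()]).
#' @param role channel role, see [channel_stack()].
#' @return a `channel_stack`.
#' @export
read_channel_stack <- function(path, role = "donor") {
  tf <- read_tiff_stack(path)
  channel_stack(tf$data, role = role, pixel_size = tf$pixel_size,
                frame_interval = tf$frame_interval,
                bit_depth = if (identical(tf$dtype, "uint16")) 16L else 32L)
}
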