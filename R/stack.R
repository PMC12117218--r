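#' Stack metadata
#'
#' Describes the acquisition grid and channel layout of a multi-channel
#' confocal stack. Volumes in this package are plain numeric arrays with a
#' fixed axis order `(z, y, x, c)`; a `stack_meta` object travels alongside
#' them.
#'
#' Defaults follow a typical laser-scanning confocal acquisition of fibrin
#' scaffolds: 77.69 nm lateral pixel size and a 100 nm axial step.
#'
#' @param pixel_size_xy Lateral pixel size in nm/pixel (> 0).
#' @param z_step Axial step size in nm (> 0).
#' @param channel_names Character vector of unique channel labels, ordered as
#'   the channel axis of the stack. Conventional labels are
#'   `c("Ref405", "Ref488", "Ref561", "Tra")` with an optional `"GT"`
#'   fluorescence channel.
#' @param dtype Storage dtype the voxels originated from (recorded so integer
#'   acquisitions survive a write/read round trip); one of `"float32"`,
#'   `"uint8"`, `"uint16"`.
#' @return An object of class `stack_meta`.
#' @export
stack_meta <- function(pixel_size_xy = 77.69, z_step = 100,
                       channel_names = c("Ref405", "Ref488", "Ref561", "Tra"),
                       dtype = "float32") {
  stopifnot(is.numeric(pixel_size_xy), length(pixel_size_xy) == 1L,
            pixel_size_xy > 0,
            is.numeric(z_step), length(z_step) == 1L, z_step > 0,
            is.character(channel_names), length(channel_names) >= 1L,
            !anyDuplicated(channel_names))
  dtype <- match.arg(dtype, c("float32", "uint8", "uint16"))
  structure(list(pixel_size_xy = as.numeric(pixel_size_xy),
                 z_step = as.numeric(z_step),
                 channel_names = channel_names,
                 dtype = dtype),
            class = "stack_meta")
}

#' @export
print.stack_meta <- function(x, ...) {
  cat("<stack_meta> pixel_size_xy:", x$pixel_size_xy, "nm, z_step:",
      x$z_step, "nm\n  channels:", paste(x$channel_names, collapse = ", "),
      "(", x$dtype, ")\n")
  invisible(x)
}

# Coerce to a 4-D (z, y, x, c) array; 3-D input is treated as single-channel.
as_stack <- function(x) {
  if (is.null(dim(x))) stop("stack must be an array")
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
  } else if (length(d) != 4L) {
    stop("stack must have dims (z, y, x) or (z, y, x, c)")
  }
  storage.mode(x) <- "double"
  x
}

check_stack <- function(stack, meta = NULL) {
  stack <- as_stack(stack)
  if (!all(is.finite(stack))) stop("stack contains non-finite values")
  if (!is.null(meta) && dim(stack)[4] != length(meta$channel_names)) {
    stop(sprintf("stack has %d channels but meta declares %d",
                 dim(stack)[4], length(meta$channel_names)))
  }
  stack
}

# Index of a named channel within a stack, resolved through meta.
channel_index <- function(meta, name) {
  i <- match(name, meta$channel_names)
  if (is.na(i)) stop(sprintf("channel '%s' absent from stack metadata", name))
  i
}

# Subset channels by name, returning the (stack, meta) pair.
select_channels <- function(stack, meta, names) {
  stack <- as_stack(stack)
  idx <- vapply(names, channel_index, integer(1), meta = meta)
  sub <- stack[, , , idx, drop = FALSE]
  m <- meta
  m$channel_names <- meta$channel_names[idx]
  list(stack = sub, meta = m)
}
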