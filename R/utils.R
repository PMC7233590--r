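## Internal helpers shared across modules.

# Run code with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards so package functions never perturb
# the session RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Convert an RGB raster to a scalar channel
#'
#' @param image numeric array `[rows, cols, 3]` (any range) or a matrix,
#'   which is returned unchanged.
#' @param channel one of `"luminance"` (Rec. 601 weights
#'   `0.299 R + 0.587 G + 0.114 B`), `"red"`, `"green"`, `"blue"`.
#' @return numeric matrix `[rows, cols]`.
#' @export
to_scalar_channel <- function(image, channel = c("luminance", "red", "green", "blue")) {
  channel <- match.arg(channel)
  if (is.matrix(image)) return(image)
  if (length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop("image must be a matrix or an array with 3 channels", call. = FALSE)
  }
  switch(channel,
    luminance = 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3],
    red = image[, , 1],
    green = image[, , 2],
    blue = image[, , 3]
  )
}

# Content hash (md5 of the serialized object, skipping the 14-byte header
# that records the serializer version) used for the reproducibility stamp in
# reports.
content_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)[-seq_len(14)]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(bytes, tf)
  unname(tools::md5sum(tf))
}

stop_oxi <- function(class, message, ...) {
  stop(structure(
    class = c(class, "oxiring_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)
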