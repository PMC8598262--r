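# Shared fixture builders. Everything is generated in code at test time.

# small, fast field of view for single-droplet tests
test_config <- function(...) {
  generator_config(image_size = 160L, ...)
}

# noiseless, background-free configuration for exactness tests
clean_config <- function(...) {
  generator_config(image_size = 160L, shot_scale = 0, read_sigma = 0,
                   bg_offset = 0, bg_gradient = 0, ...)
}

# a bare synthetic disk (value `height` on zero background), no cells
make_disk <- function(n = 128, radius = 50, height = 100, center = NULL) {
  if (is.null(center)) center <- c(n / 2, n / 2)
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  disk <- ((rows - center[1])^2 + (cols - center[2])^2) <= radius^2
  disk * height
}

# Gaussian blobs at given (row, col) centers on an n x n zero field
make_blobs <- function(centers, n = 128, sigma = 2, amp = 100) {
  img <- matrix(0, n, n)
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1]; c0 <- centers[k, 2]
    img <- img + amp * exp(-(outer((seq_len(n) - r0)^2,
                                   (seq_len(n) - c0)^2, "+")) /
                             (2 * sigma^2))
  }
  img
}

logical_mask <- function(img, thr = 0) img > thr
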