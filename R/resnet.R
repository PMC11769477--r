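# Structural model of the canonical 50-layer residual backbone: per-layer
# output shapes and variable counts. Convolutions carry biases; every batch
# normalization contributes 4 variables per channel (scale, offset, moving
# mean, moving variance), of which 2 are trainable. This is the counting
# convention under which the backbone totals 23,587,712 variables for any
# stride-32-compatible input.

#' Per-layer report for the 50-layer residual backbone
#'
#' Enumerates the stem (7x7/64 convolution + batch norm + 3x3 max pool) and
#' the four bottleneck stages (3, 4, 6 and 3 blocks with inner widths 64,
#' 128, 256 and 512), tracking output shapes and variable counts. The head
#' is excluded; the final output shape is `H/32 x W/32 x 2048`.
#'
#' @param height,width Input spatial dimensions; must be multiples of 32.
#' @return A `data.frame` with columns `name`, `out_h`, `out_w`,
#'   `channels`, `params` (all variables, normalization statistics
#'   included) and `trainable` (excluding moving statistics).
#' @export
resnet50_layer_report <- function(height = 320L, width = 320L) {
  if (height %% 32 != 0 || width %% 32 != 0) {
    stop_validation(
      "input %dx%d is not divisible by the backbone's stride-32 downsampling",
      height, width
    )
  }
  rows <- list()
  add <- function(name, h, w, ch, params, trainable = params) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, out_h = h, out_w = w, channels = ch,
      params = params, trainable = trainable, stringsAsFactors = FALSE
    )
  }
  conv_p <- function(k, cin, cout) k * k * cin * cout + cout

  h <- height %/% 2L; w <- width %/% 2L
  add("conv1_conv", h, w, 64L, conv_p(7, 3, 64))
  add("conv1_bn", h, w, 64L, 4L * 64L, 2L * 64L)
  h <- height %/% 4L; w <- width %/% 4L
  add("pool1_pool", h, w, 64L, 0L)

  widths <- c(64L, 128L, 256L, 512L)
  blocks <- c(3L, 4L, 6L, 3L)
  cin <- 64L
  for (s in seq_along(widths)) {
    f <- widths[s]
    fout <- 4L * f
    if (s > 1) { h <- h %/% 2L; w <- w %/% 2L }
    for (b in seq_len(blocks[s])) {
      tag <- sprintf("conv%d_block%d", s + 1L, b)
      if (b == 1L) {
        add(paste0(tag, "_0_conv"), h, w, fout, conv_p(1, cin, fout))
        add(paste0(tag, "_0_bn"), h, w, fout, 4L * fout, 2L * fout)
      }
      add(paste0(tag, "_1_conv"), h, w, f, conv_p(1, cin, f))
      add(paste0(tag, "_1_bn"), h, w, f, 4L * f, 2L * f)
      add(paste0(tag, "_2_conv"), h, w, f, conv_p(3, f, f))
      add(paste0(tag, "_2_bn"), h, w, f, 4L * f, 2L * f)
      add(paste0(tag, "_3_conv"), h, w, fout, conv_p(1, f, fout))
      add(paste0(tag, "_3_bn"), h, w, fout, 4L * fout, 2L * fout)
      cin <- fout
    }
  }
  do.call(rbind, rows)
}
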