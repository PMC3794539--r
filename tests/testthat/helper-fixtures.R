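# Shared fixtures, all generated in code at test time.

# smooth isotropic Gaussian blob, background 0
gaussian_blob <- function(n = 32, spacing = 1, amplitude = 100, width = 40) {
  co <- (seq_len(n) - 1 - (n - 1) / 2) * spacing
  g <- exp(-co^2 / width)
  srr_volume(amplitude * outer(outer(g, g), g), spacing = spacing,
             meta = list(background = 0))
}

simulate_plan <- function(vol, plan, model, seed = NULL) {
  lapply(seq_len(nrow(plan)), function(k) {
    simulate_lr_stack(vol, plan[k, ], model,
                      seed = if (is.null(seed)) NULL else seed + k)
  })
}

rms_diff <- function(a, b) {
  if (inherits(a, "srr_volume")) a <- a$data
  if (inherits(b, "srr_volume")) b <- b$data
  sqrt(mean((a - b)^2))
}

# noiseless logistic edge profile sampled at step px
logistic_profile <- function(a1 = 0, a2 = 1, a3 = 4.4, a4 = 10,
                             x_max = 2 * a4, step = 0.25) {
  x <- seq(0, x_max, by = step)
  tibble::tibble(s_px = x, value = a1 + a2 / (1 + exp(-a3 * (x - a4))))
}
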