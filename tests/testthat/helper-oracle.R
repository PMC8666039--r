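# Brute-force fitting oracle, independent of the package's optimizer.
#
# The 5PL model is linear in (c, d) once (b, e, f) are fixed:
#   y = c * (1 - g) + d * g,   g = 1 / (1 + exp(b (ln x - ln e)))^f
# so a coarse grid over (b, e, f) with a closed-form least-squares solve
# for (c, d) bounds the attainable RSS from below.
oracle_grid_rss <- function(x, y,
                            b_grid = seq(-30, -2, length.out = 25),
                            e_grid = NULL,
                            f_grid = exp(seq(log(0.2), log(5),
                                             length.out = 15))) {
  if (is.null(e_grid)) {
    e_grid <- seq(min(x), max(x), length.out = 40)
  }
  best <- Inf
  for (b in b_grid) {
    for (e in e_grid) {
      lg <- b * (log(x) - log(e))
      for (f in f_grid) {
        g <- 1 / (1 + exp(lg))^f
        X <- cbind(1 - g, g)
        cf <- tryCatch(qr.coef(qr(X), y), error = function(err) NULL)
        if (is.null(cf) || anyNA(cf)) next
        rss <- sum((y - X %*% cf)^2)
        if (rss < best) best <- rss
      }
    }
  }
  best
}
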