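# Dinucleotide-level sequence synthesis.
#
# A first-order Markov chain over A/C/G/T whose single non-trivial row (the
# transitions out of C) is scaled so that the realised CpG observed/expected
# ratio hits a target while the stationary base composition hits a target GC
# fraction. Because depressing C->G perturbs the stationary distribution, the
# working targets are adjusted by fixed-point iteration on the analytic
# stationary distribution before any sequence is drawn.

#' @noRd
markov_matrix <- function(gc, oe) {
  gc_w <- max(min(gc, 0.98), 0.02)
  oe_w <- max(oe, 0)
  for (iter in 1:40) {
    p <- c(A = (1 - gc_w) / 2, C = gc_w / 2, G = gc_w / 2, T = (1 - gc_w) / 2)
    trans <- matrix(rep(p, each = 4), nrow = 4, dimnames = list(names(p), names(p)))
    pg_c <- min(oe_w * p[["G"]], 0.95)
    other <- p[c("A", "C", "T")] / sum(p[c("A", "C", "T")])
    trans["C", ] <- c(other[["A"]], other[["C"]], 0, other[["T"]]) * (1 - pg_c)
    trans["C", "G"] <- pg_c
    # stationary distribution of the 4-state chain
    ev <- eigen(t(trans))
    pi_s <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
    pi_s <- pi_s / sum(pi_s)
    names(pi_s) <- names(p)
    gc_real <- pi_s[["C"]] + pi_s[["G"]]
    oe_real <- if (pi_s[["C"]] * pi_s[["G"]] > 0) {
      pi_s[["C"]] * trans["C", "G"] / (pi_s[["C"]] * pi_s[["G"]])
    } else 0
    if (abs(gc_real - gc) < 1e-4 && (oe == 0 || abs(oe_real - oe) < 1e-4)) break
    gc_w <- max(min(gc_w * ifelse(gc_real > 0, gc / gc_real, 1), 0.98), 0.02)
    if (oe_real > 0 && oe > 0) oe_w <- oe_w * oe / oe_real
  }
  list(trans = trans, init = pi_s)
}

# Draw one sequence of length n; uniforms come from R's RNG so set.seed()
# upstream makes the output reproducible byte-for-byte.
#' @noRd
draw_markov_seq <- function(n, gc, oe) {
  mm <- markov_matrix(gc, oe)
  markov_seq_cpp(t(apply(mm$trans, 1, cumsum)), cumsum(mm$init), runif(n))
}

# Rejection-sample until measured GC and O/E land within `band` of target
# (composition guarantee for synthetic islands); returns closest attempt if
# the band is never hit within `max_tries`.
#' @noRd
draw_seq_calibrated <- function(n, gc, oe, band = 0.05, max_tries = 30L) {
  best <- NULL
  best_err <- Inf
  for (i in seq_len(max_tries)) {
    s <- draw_markov_seq(n, gc, oe)
    err <- max(abs(gc_fraction(s) - gc), abs(cpg_oe_ratio(s) - oe))
    if (err < best_err) {
      best <- s
      best_err <- err
    }
    if (best_err <= band) break
  }
  if (best_err > band) {
    warn(sprintf(
      "sequence composition off target by %.3f after %d draws (target GC %.2f, O/E %.2f)",
      best_err, max_tries, gc, oe
    ))
  }
  best
}
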