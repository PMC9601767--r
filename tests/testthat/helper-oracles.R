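# Independent brute-force oracles. These deliberately avoid the closed-form
# index arithmetic, cumulative-sum sweeps and rank formulas used by the
# package internals.

# mirrored-window mean by explicit index reflection, one position at a time
brute_mirror_mean <- function(values, window, mirror = "reflect") {
  n <- length(values)
  h <- (window - 1) %/% 2
  reflect <- function(j) {
    if (n == 1) return(1)
    j <- j - 1  # 0-based
    repeat {
      if (j < 0) {
        j <- if (mirror == "reflect") -j else -j - 1
      } else if (j >= n) {
        j <- if (mirror == "reflect") 2 * (n - 1) - j else 2 * n - 1 - j
      } else {
        break
      }
    }
    j + 1
  }
  vapply(seq_len(n), function(i) {
    mean(vapply((i - h):(i + h), function(j) values[reflect(j)], 0))
  }, 0)
}

# AUC by counting positive-negative score pairs (ties worth one half)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# maximum F1 by evaluating every distinct score cut (plus 0 and 1) with
# direct vector comparisons
brute_fmax <- function(scores, labels) {
  cuts <- sort(unique(c(scores, 0, 1)))
  best <- 0
  for (t in cuts) {
    call <- scores >= t
    tp <- sum(call & labels == 1)
    fp <- sum(call & labels == 0)
    fn <- sum(!call & labels == 1)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    best <- max(best, f1)
  }
  best
}

# dense random-direction sampling SASA for tiny systems
brute_sasa <- function(xyz, radii_per_atom, probe = 1.4, n = 1e5) {
  R <- radii_per_atom + probe
  m <- nrow(xyz)
  out <- numeric(m)
  for (i in seq_len(m)) {
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    p <- sweep(v * R[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n)
    for (j in seq_len(m)[-i]) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 >= R[j]^2
    }
    out[i] <- mean(exposed) * 4 * pi * R[i]^2
  }
  out
}

# shared tiny fixtures
tiny_pdb_path <- function() {
  system.file("extdata", "tiny_model.pdb", package = "afdisorder")
}
tiny_cif_path <- function() {
  system.file("extdata", "tiny_model.cif", package = "afdisorder")
}
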