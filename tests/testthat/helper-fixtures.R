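# shared small fixtures and oracles

tiny_spec <- function(seed = 1L, ...) {
  phantom_spec(image_size = 64L, seed = seed, ...)
}

# deterministic random matrix
rmat <- function(n, m, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * m), n, m)
}

# brute-force global histogram equalization oracle
global_he_oracle <- function(x, levels) {
  h <- tabulate(as.integer(x) + 1L, nbins = levels)
  cdf <- cumsum(h) / sum(h)
  matrix(cdf[as.integer(x) + 1L] * (levels - 1), nrow(x), ncol(x))
}

# O(n^2) pair-counting AUROC oracle
auroc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# plain-loop Horn-clause interpreter oracle
rule_interpreter_oracle <- function(values, rules) {
  fired <- list()
  for (r in rules) {
    ok <- TRUE
    for (a in r$antecedents) {
      v <- values[[a$cue]]
      op <- if (is.null(a$op)) ">" else a$op
      if (op == ">" && !(v > a$threshold)) ok <- FALSE
      if (op == "<" && !(v < a$threshold)) ok <- FALSE
      if (!ok) break
    }
    if (ok) {
      fired[[length(fired) + 1L]] <- list(id = r$id, predicate = r$consequent,
                                          confidence = values[[r$confidence]])
    }
  }
  fired
}
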