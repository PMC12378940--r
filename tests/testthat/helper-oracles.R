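# Independent brute-force oracles, kept deliberately naive so they cannot
# share a defect with the implementation they check.

# Betweenness centrality by exhaustive simple-path enumeration (tiny graphs
# only). Endpoints are excluded from the paths they terminate.
brute_betweenness <- function(edges) {
  nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])))
  all_paths <- function(s, t, visited) {
    if (s == t) return(list(visited))
    out <- list()
    for (nb in setdiff(adj[[s]], visited))
      out <- c(out, all_paths(nb, t, c(visited, nb)))
    out
  }
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  pairs <- utils::combn(nodes, 2)
  for (i in seq_len(ncol(pairs))) {
    s <- pairs[1, i]; t <- pairs[2, i]
    paths <- all_paths(s, t, s)
    if (!length(paths)) next
    len <- vapply(paths, length, integer(1))
    shortest <- paths[len == min(len)]
    sigma <- length(shortest)
    inner <- unlist(lapply(shortest, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      tab <- table(inner)
      btw[names(tab)] <- btw[names(tab)] + as.numeric(tab) / sigma
    }
  }
  btw
}

# Topological overlap by explicit double loop over shared neighbours.
brute_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- sum(a[i, ] * a[, j])
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# Upper-tail hypergeometric probability by direct enumeration of the
# sampling distribution.
brute_hyper_tail <- function(k, N, m, n) {
  js <- k:min(m, n)
  sum(choose(m, js) * choose(N - m, n - js)) / choose(N, n)
}

# Weighted median by scanning the cumulative weight, no interpolation
# subtleties shared with the implementation: evaluated on duplicated-mass
# inputs where the two definitions agree.
brute_weighted_median <- function(x, w, grain = 1000L) {
  # expand each value proportionally to its weight and take a plain median
  reps <- round(w / sum(w) * grain)
  stats::median(rep(x, times = pmax(reps, 0L)))
}

# One-component PLS1 on autoscaled data: the closed-form direction X'y.
brute_pls_scores <- function(X, y01) {
  Xs <- scale(X)
  yc <- y01 - mean(y01)
  w <- drop(crossprod(Xs, yc)); w <- w / sqrt(sum(w^2))
  drop(Xs %*% w)
}

# Direct-sum Cochran Q over Wald ratios.
brute_cochran_q <- function(rows, beta) {
  w <- rows$beta_exp^2 / rows$se_out^2
  sum(w * (rows$beta_out / rows$beta_exp - beta)^2)
}

# Build an instrument data.frame from plain vectors.
make_rows <- function(bx, by, sy, sx = 0.01, n_exp = 8299, n_out = 494164) {
  k <- length(bx)
  data.frame(snp = sprintf("rs%03d", seq_len(k)), beta_exp = bx, se_exp = sx,
             p_exp = 1e-8, beta_out = by, se_out = sy, p_out = 0.5,
             eaf = 0.3, n_exp = n_exp, n_out = n_out,
             stringsAsFactors = FALSE)
}

# A tiny pathway_db with a fully controlled universe.
toy_db <- function() {
  sets <- list(pw1 = c("C00001", "C00002", "C00003"),
               pw2 = c("C00004", "C00005", "C00006", "C00007"))
  graphs <- list(
    pw1 = data.frame(node1 = c("C00001", "C00002"),
                     node2 = c("C00002", "C00003")),
    pw2 = data.frame(node1 = c("C00004", "C00004", "C00004"),
                     node2 = c("C00005", "C00006", "C00007")))
  pathway_db(sets, graphs)
}
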