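# Shared fixtures built in code.

# a small deterministic genome with hand-placed tracks
toy_genome <- function() {
  karyo_genome(
    tibble::tibble(chrom = c("c1", "c2"), length = c(10000, 6000)),
    tracks = list(
      CNE = tibble::tibble(chrom = c("c1", "c1", "c2"),
                           start = c(1000, 5500, 100),
                           end = c(2000, 5600, 400)),
      msHSB = tibble::tibble(chrom = "c1", start = 2000, end = 8000)
    )
  )
}

# brute-force N50 straight from the definition
n50_oracle <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  for (i in seq_along(s)) if (sum(s[seq_len(i)]) >= half) return(s[i])
}

# independent exact Mann-Whitney p by enumerating index subsets on raw values
mwu_oracle <- function(x, y, sides = "two.sided") {
  n1 <- length(x); N <- n1 + length(y)
  pooled <- c(x, y)
  u_of <- function(ii) {
    xx <- pooled[ii]; yy <- pooled[-ii]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(N, n1), 2, u_of)
  pl <- mean(us <= u_obs + 1e-9); pg <- mean(us >= u_obs - 1e-9)
  switch(sides, less = pl, greater = pg,
         two.sided = min(1, 2 * min(pl, pg)))
}

# independent per-input BFS for signed reversal distance
reversal_bfs_oracle <- function(perm) {
  target <- paste(seq_along(perm), collapse = " ")
  key <- paste(perm, collapse = " ")
  if (key == target) return(0L)
  seen <- new.env(hash = TRUE)
  assign(key, TRUE, envir = seen)
  frontier <- list(perm)
  d <- 0L
  repeat {
    d <- d + 1L
    nxt <- list()
    for (p in frontier) {
      n <- length(p)
      for (i in 1:n) for (j in i:n) {
        q <- p
        q[i:j] <- -rev(p[i:j])
        k <- paste(q, collapse = " ")
        if (k == target) return(d)
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          nxt[[length(nxt) + 1]] <- q
        }
      }
    }
    frontier <- nxt
  }
}

# all signed permutations of 1..n
all_signed_perms <- function(n) {
  perms <- combinat_perms(seq_len(n))
  out <- list()
  signs <- expand.grid(rep(list(c(1, -1)), n))
  for (p in perms) for (si in seq_len(nrow(signs))) {
    out[[length(out) + 1]] <- p * as.numeric(signs[si, ])
  }
  out
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# default-scale simulation config used across module tests; overrides win
test_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_macro = 3, n_micro = 5,
         macro_len_range = c(3e6, 5e6),
         micro_len_range = c(6e5, 1.5e6),
         n_scaffolds = 40, bac_spacing = 6e4,
         min_inversion_size = 1.5e5),
    list(...)
  )
  do.call(sim_config, args)
}

# pipeline params matched to the scaled-down genomes
test_params <- function() assembly_params(resolution = 10000)
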