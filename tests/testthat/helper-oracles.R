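# Independent oracles and fixture builders used across the test files.
# These deliberately re-derive expected values with simple brute-force code
# that shares nothing with the package implementation.

# stack-based bracket matcher, one family at a time
oracle_match_family <- function(db, open, close) {
  chars <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pairs <- list()
  for (k in seq_along(chars)) {
    if (chars[k] == open) stack <- c(stack, k)
    else if (chars[k] == close) {
      pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(pairs) == 0) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, pairs)
  m[order(m[, 1]), , drop = FALSE]
}

# exhaustive pair-stacking partition: two pairs stack iff (i+1, j-1)
oracle_stems <- function(pairs) {
  if (nrow(pairs) == 0) return(list())
  key <- paste(pairs[, 1], pairs[, 2])
  groups <- list()
  for (r in order(pairs[, 1])) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    placed <- FALSE
    for (g in seq_along(groups)) {
      last <- groups[[g]][nrow(groups[[g]]), ]
      if (last[1] + 1 == i && last[2] - 1 == j) {
        groups[[g]] <- rbind(groups[[g]], c(i, j))
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- matrix(c(i, j), 1)
  }
  groups
}

# dot-product angle oracle in degrees
oracle_angle <- function(u, v)
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_star <- function(star, R, t = c(0, 0, 0)) {
  star$center <- as.vector(R %*% star$center) + t
  star$endpoints <- t(apply(star$endpoints, 1, function(p)
    as.vector(R %*% p) + t))
  star
}

# feasible random angle triples: pairwise angles of three random unit
# vectors are feasible by construction
random_feasible_angles <- function() {
  repeat {
    u <- matrix(stats::rnorm(9), 3)
    u <- u / sqrt(rowSums(u^2))
    a <- c(oracle_angle(u[1, ], u[2, ]), oracle_angle(u[2, ], u[3, ]),
           oracle_angle(u[3, ], u[1, ]))
    if (all(a > 2 & a < 178)) return(a)
  }
}

# a two-junction chain: two single-3WJ cassettes in tandem
TANDEM_3WJ_DB <- paste0("((.((...)).((...)).))",
                        "((.((...)).((...)).))")
TANDEM_3WJ_SEQ <- paste(rep("A", nchar(TANDEM_3WJ_DB)), collapse = "")

# small single-3WJ fixture used in several files
FIX3WJ_DB <- "..((..((...))..((...))..)).."
FIX3WJ_SEQ <- "GGCCAAGGAAACCAAGGAAACCAAGGCC"

quick_spec <- function(count, seed, sigma = 5)
  synthetic_spec(count = count, seed = seed, sigma = sigma)

# internal autograd handles used by the gradient-check tests
ag_const <- rna3wj:::ag_const
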