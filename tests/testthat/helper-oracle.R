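# Direct loop transliterations of the two-phase algorithm, kept
# deliberately naive (explicit quadruple loops, no vectorization) to
# serve as an independent oracle for the package implementation.

oracle_separation <- function(mats) {
  N <- length(mats)
  lapply(seq_len(N), function(n) {
    Tn <- mats[[n]]
    D <- matrix(0, nrow(Tn), ncol(Tn))
    for (i in seq_len(nrow(Tn))) {
      for (l in seq_len(ncol(Tn))) {
        per_m <- c()
        for (m in seq_len(N)) {
          if (m == n) next
          d_mj <- numeric(nrow(mats[[m]]))
          for (j in seq_len(nrow(mats[[m]]))) {
            d_mj[j] <- abs(Tn[i, l] - mats[[m]][j, l])
          }
          per_m <- c(per_m, sum(d_mj) / length(d_mj))
        }
        D[i, l] <- sum(per_m) / length(per_m)
      }
    }
    D
  })
}

# stable descending sort of x: ties keep ascending original index
oracle_order_desc <- function(x) {
  idx <- seq_along(x)
  idx[order(-x, idx)]
}
oracle_order_asc <- function(x) {
  idx <- seq_along(x)
  idx[order(x, idx)]
}

oracle_training <- function(mats, K) {
  D <- oracle_separation(mats)
  out <- lapply(seq_along(mats), function(n) {
    Tn <- mats[[n]]
    tmpl <- matrix(0, K, ncol(Tn))
    prov <- matrix(0L, K, ncol(Tn))
    for (l in seq_len(ncol(Tn))) {
      idx <- oracle_order_desc(D[[n]][, l])
      for (k in seq_len(K)) {
        tmpl[k, l] <- Tn[idx[k], l]
        prov[k, l] <- idx[k]
      }
    }
    list(templates = tmpl, provenance = prov)
  })
  list(templates = lapply(out, `[[`, "templates"),
       provenance = lapply(out, `[[`, "provenance"))
}

oracle_matching <- function(tlist, Q, F_, S) {
  N <- length(tlist)
  L <- ncol(Q)
  S <- min(S, nrow(Q))
  final <- list(); qrec <- list()
  for (n in seq_len(N)) {
    Tp <- tlist[[n]]
    K <- nrow(Tp)
    Fn <- min(F_, K)
    Tf <- matrix(0, Fn, L)
    Qr <- matrix(0, S, L)
    for (l in seq_len(L)) {
      e <- matrix(0, K, nrow(Q))
      for (k in seq_len(K)) for (r in seq_len(nrow(Q))) {
        e[k, r] <- abs(Tp[k, l] - Q[r, l])
      }
      a <- numeric(K)
      for (k in seq_len(K)) a[k] <- sum(e[k, ]) / ncol(e)
      b <- numeric(nrow(Q))
      for (r in seq_len(nrow(Q))) b[r] <- sum(e[, r]) / nrow(e)
      ia <- oracle_order_asc(a)
      ib <- oracle_order_asc(b)
      for (f in seq_len(Fn)) Tf[f, l] <- Tp[ia[f], l]
      for (s in seq_len(S)) Qr[s, l] <- Q[ib[s], l]
    }
    final[[n]] <- Tf
    qrec[[n]] <- Qr
  }
  list(final = final, queries = qrec)
}

oracle_classify <- function(final, qrec) {
  N <- length(final)
  pooled <- do.call(rbind, qrec)
  assigned <- integer(nrow(pooled))
  dists <- matrix(0, nrow(pooled), N)
  for (s in seq_len(nrow(pooled))) {
    for (n in seq_len(N)) {
      best <- Inf
      for (f in seq_len(nrow(final[[n]]))) {
        d <- sum(abs(final[[n]][f, ] - pooled[s, ]))
        if (d < best) best <- d
      }
      dists[s, n] <- best
    }
    assigned[s] <- which.min(dists[s, ])
  }
  votes <- tabulate(assigned, N)
  class_scores <- apply(dists, 2, min)
  top <- which(votes == max(votes))
  winner <- top[which.min(class_scores[top])]
  list(assigned = assigned, decision = winner, votes = votes,
       class_scores = class_scores)
}

oracle_verification <- function(final, qrec) {
  vapply(seq_along(final), function(n) {
    best <- Inf
    for (s in seq_len(nrow(qrec[[n]]))) {
      for (f in seq_len(nrow(final[[n]]))) {
        d <- sum(abs(final[[n]][f, ] - qrec[[n]][s, ]))
        if (d < best) best <- d
      }
    }
    best
  }, numeric(1))
}

# convert a list of per-class matrices into the package's table form
mats_to_df <- function(mats) {
  dplyr::bind_rows(lapply(seq_along(mats), function(n) {
    m <- mats[[n]]
    colnames(m) <- sprintf("f%d", seq_len(ncol(m)))
    dplyr::bind_cols(tibble::tibble(class = sprintf("c%d", n)),
                     tibble::as_tibble(as.data.frame(m)))
  }))
}

# random small problem instance with valid K/F/S
random_case <- function(seed) {
  set.seed(seed)
  N <- sample(2:4, 1)
  L <- sample(1:6, 1)
  I <- sample(2:12, N, replace = TRUE)
  mats <- lapply(I, function(i) matrix(round(rnorm(i * L), 3), i, L))
  R <- sample(1:5, 1)
  Q <- matrix(round(rnorm(R * L), 3), R, L)
  K <- sample(seq_len(min(I)), 1)
  F_ <- sample(seq_len(K), 1)
  S <- sample(1:5, 1)
  list(mats = mats, Q = Q, K = K, F = F_, S = S)
}

# compare package output against the oracle on one random case;
# returns TRUE when every stage matches bit-identically
oracle_equivalent <- function(case) {
  or_tr <- oracle_training(case$mats, case$K)
  or_mt <- oracle_matching(or_tr$templates, case$Q, case$F, case$S)
  or_cl <- oracle_classify(or_mt$final, or_mt$queries)

  cfg <- iatr_config(K = case$K, n_final = case$F, n_query = case$S)
  tm <- iatr_train(mats_to_df(case$mats), cfg)
  mt <- iatr_match(tm, case$Q)
  res <- iatr_classify(mt)

  classes <- sprintf("c%d", seq_along(case$mats))
  identical(lapply(tm$templates, unname),
            setNames(or_tr$templates, classes)) &&
    identical(lapply(tm$provenance, unname),
              setNames(or_tr$provenance, classes)) &&
    identical(lapply(mt$final, unname), setNames(or_mt$final, classes)) &&
    identical(lapply(mt$queries, unname),
              setNames(or_mt$queries, classes)) &&
    identical(match(res$assignments$assigned, classes), or_cl$assigned) &&
    identical(res$decision, classes[or_cl$decision]) &&
    identical(res$votes$score, or_cl$class_scores)
}

# TRUE when no two instances of a class share a separation score in any
# dimension (the scope of the order-invariance property: with N > 2
# classes, values lying between the other classes' ranges tie exactly)
sep_tie_free <- function(mats) {
  D <- oracle_separation(mats)
  all(vapply(D, function(m) {
    all(apply(m, 2, function(col) !any(duplicated(col))))
  }, logical(1)))
}
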