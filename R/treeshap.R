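# Exact Shapley attribution for gradient-boosted trees, evaluated in double
# precision from the dumped tree structure. Implements the polynomial-time
# tree-path algorithm (EXTEND/UNWIND over the active decision path, with
# node covers as the background weights), so per-sample additivity
# bias + sum(shap) == margin holds to round-off rather than to the
# single-precision tolerance of the booster's built-in contribution pass.

# boosters compare features in single precision; round inputs the same way
# so threshold-adjacent samples route through the same branch
round_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L),
          "numeric", n = length(x), size = 4L)
}

parse_booster_trees <- function(booster, feature_names) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  val_col <- if ("Gain" %in% names(dt)) "Gain" else "Quality"
  lapply(split(dt, dt$Tree), function(tr) {
    tr <- tr[order(tr$Node), , drop = FALSE]
    id2node <- stats::setNames(tr$Node + 1L, tr$ID)
    is_leaf <- tr$Feature == "Leaf"
    list(is_leaf = is_leaf,
         feature = ifelse(is_leaf, NA_integer_,
                          match(tr$Feature, feature_names)),
         split = round_float32(as.numeric(tr$Split)),
         yes = ifelse(is_leaf, NA_integer_, unname(id2node[tr$Yes])),
         no = ifelse(is_leaf, NA_integer_, unname(id2node[tr$No])),
         value = ifelse(is_leaf, as.numeric(tr[[val_col]]), NA_real_),
         cover = as.numeric(tr$Cover))
  })
}

tree_leaf_value <- function(tree, x) {
  j <- 1L
  while (!tree$is_leaf[j]) {
    f <- tree$feature[j]
    j <- if (x[f] < tree$split[j]) tree$yes[j] else tree$no[j]
  }
  tree$value[j]
}

# one tree, one sample: returns phi over features
treeshap_one <- function(tree, x, n_features) {
  phi <- numeric(n_features)

  extend <- function(m, pz, po, pi) {
    l <- nrow(m)
    m <- rbind(m, c(pi, pz, po, if (l == 0L) 1 else 0))
    if (l > 0L) for (i in l:1) {
      m[i + 1L, 4L] <- m[i + 1L, 4L] + po * m[i, 4L] * i / (l + 1)
      m[i, 4L] <- pz * m[i, 4L] * (l + 1 - i) / (l + 1)
    }
    m
  }
  unwind <- function(m, i) {
    l <- nrow(m)
    n <- m[l, 4L]
    o_i <- m[i, 3L]; z_i <- m[i, 2L]
    if (l >= 2L) for (j in (l - 1L):1L) {
      if (o_i != 0) {
        t <- m[j, 4L]
        m[j, 4L] <- n * l / (j * o_i)
        n <- t - m[j, 4L] * z_i * (l - j) / l
      } else {
        m[j, 4L] <- m[j, 4L] * l / (z_i * (l - j))
      }
    }
    if (i < l) m[i:(l - 1L), 1:3] <- m[(i + 1L):l, 1:3, drop = FALSE]
    m[-l, , drop = FALSE]
  }
  unwound_sum <- function(m, i) {
    # sum of weights after unwinding entry i, without materializing it
    l <- nrow(m)
    o_i <- m[i, 3L]; z_i <- m[i, 2L]
    total <- 0
    n <- m[l, 4L]
    if (l >= 2L) for (j in (l - 1L):1L) {
      if (o_i != 0) {
        tmp <- n * l / (j * o_i)
        total <- total + tmp
        n <- m[j, 4L] - tmp * z_i * (l - j) / l
      } else {
        total <- total + m[j, 4L] * l / (z_i * (l - j))
      }
    }
    total
  }

  recurse <- function(j, m, pz, po, pi) {
    m <- extend(m, pz, po, pi)
    if (tree$is_leaf[j]) {
      l <- nrow(m)
      if (l >= 2L) for (i in 2:l) {
        w <- unwound_sum(m, i)
        d <- m[i, 1L]
        phi[d] <<- phi[d] + w * (m[i, 3L] - m[i, 2L]) * tree$value[j]
      }
      return(invisible())
    }
    f <- tree$feature[j]
    hot <- if (x[f] < tree$split[j]) tree$yes[j] else tree$no[j]
    cold <- if (hot == tree$yes[j]) tree$no[j] else tree$yes[j]
    iz <- 1; io <- 1
    k <- which(m[, 1L] == f)
    if (length(k)) {
      k <- k[1L]
      iz <- m[k, 2L]; io <- m[k, 3L]
      m <- unwind(m, k)
    }
    rj <- tree$cover[j]
    recurse(hot, m, iz * tree$cover[hot] / rj, io, f)
    recurse(cold, m, iz * tree$cover[cold] / rj, 0, f)
    invisible()
  }

  m0 <- matrix(numeric(0), 0, 4)  # columns: d, z, o, w
  recurse(1L, m0, 1, 1, 0)
  phi
}

#' Exact double-precision Shapley values for a trained booster
#'
#' @param booster an \code{xgb.Booster}.
#' @param features samples x features matrix with the training column order.
#' @return list with \code{shap} (samples x features), \code{bias}
#'   (per-sample expected margin) and \code{margin} (per-sample margin
#'   recomputed in double precision); \code{bias + rowSums(shap) == margin}
#'   to round-off.
#' @keywords internal
treeshap_exact <- function(booster, features) {
  features <- as.matrix(features)
  fn <- colnames(features)
  trees <- parse_booster_trees(booster, fn)
  n <- nrow(features); p <- ncol(features)
  margin32 <- stats::predict(booster, features, outputmargin = TRUE)
  features <- matrix(round_float32(features), n, p,
                     dimnames = dimnames(features))

  # expected margin of each tree = cover-weighted leaf mean
  tree_expect <- vapply(trees, function(tr) {
    leaves <- which(tr$is_leaf)
    sum(tr$value[leaves] * tr$cover[leaves]) / tr$cover[1L]
  }, numeric(1))

  margin_trees <- vapply(seq_len(n), function(i) {
    sum(vapply(trees, tree_leaf_value, numeric(1), x = features[i, ]))
  }, numeric(1))
  # the global intercept (transformed base score): constant across samples
  base_margin <- mean(margin32 - margin_trees)

  shap <- matrix(0, n, p, dimnames = list(rownames(features), fn))
  for (i in seq_len(n)) {
    x <- features[i, ]
    for (tr in trees) shap[i, ] <- shap[i, ] + treeshap_one(tr, x, p)
  }
  bias <- rep(base_margin + sum(tree_expect), n)
  list(shap = shap, bias = bias, margin = base_margin + margin_trees)
}
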