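# Distance-based community comparison with permutation inference implemented
# in-package. Rows are (dataset x assignment type) species profiles, distances
# are presence/absence Jaccard, and group labels (continent or assignment
# type) are tested by PERMANOVA, ANOSIM, a multivariate-dispersion test, and
# db-RDA; ordination by PCoA and Kruskal NMDS. Permutations are free label
# shuffles; p-values use the (1 + count)/(1 + n_perm) estimator so p >=
# 1/(n_perm + 1); an `exact` mode enumerates all distinct label assignments.

#' Build a presence/absence occurrence matrix over a collection
#'
#' One row per dataset x assignment type: `original` (the original species
#' list), `global_reanalysis` (uncorrected reanalyzed species), and
#' `basin_reanalysis` (basin-corrected). Datasets lacking a requested type
#' (e.g., no original species list) contribute no row for that type, with a
#' warning.
#'
#' @param collection an `edna_collection`.
#' @param assignment_types subset of the three types.
#' @return an `occurrence_matrix`: tibble with metadata columns `row_id`,
#'   `dataset_id`, `assignment_type`, `continent` followed by one 0/1 column
#'   per species (the union over all profiles).
#' @export
build_occurrence_matrix <- function(collection,
                                    assignment_types = c("original",
                                                         "global_reanalysis",
                                                         "basin_reanalysis")) {
  collection <- index_pools(harmonize_collection(collection))
  ds <- collection$datasets
  if (nrow(ds) < 2) abort("need at least 2 datasets")
  assignment_types <- match.arg(assignment_types, several.ok = TRUE)
  profiles <- list()
  for (i in seq_len(nrow(ds))) {
    id <- ds$dataset_id[i]
    assigned <- resolved_species(ds$reads[[i]])
    for (type in assignment_types) {
      sp <- switch(type,
        original = ds$original_species[[i]],
        global_reanalysis = assigned,
        basin_reanalysis = intersect(assigned,
                                     dataset_pool(collection, id, "basin"))
      )
      if (!length(sp)) {
        warn(paste0("dataset ", id, " lacks assignment type '", type,
                    "'; row omitted"))
        next
      }
      profiles[[paste(id, type, sep = ".")]] <-
        list(dataset_id = id, assignment_type = type,
             continent = ds$continent[i], species = sp)
    }
  }
  universe <- sort(unique(unlist(map(profiles, "species"))))
  mat <- t(vapply(profiles, function(p) as.integer(universe %in% p$species),
                  integer(length(universe))))
  colnames(mat) <- universe
  meta <- tibble(
    row_id = names(profiles),
    dataset_id = map_chr(profiles, "dataset_id"),
    assignment_type = map_chr(profiles, "assignment_type"),
    continent = map_chr(profiles, "continent")
  )
  out <- dplyr::bind_cols(meta, as_tibble(mat))
  attr(out, "meta_cols") <- names(meta)
  class(out) <- c("occurrence_matrix", class(out))
  out
}

occ_binary <- function(occ) {
  meta <- attr(occ, "meta_cols") %||%
    intersect(c("row_id", "dataset_id", "assignment_type", "continent"),
              names(occ))
  m <- as.matrix(occ[, setdiff(names(occ), meta), drop = FALSE])
  rownames(m) <- if ("row_id" %in% names(occ)) occ$row_id else NULL
  m
}

#' Jaccard distance matrix from an occurrence matrix
#'
#' `d_ij = 1 - |A inter B| / |A union B|` on the row supports.
#'
#' @param occ an [build_occurrence_matrix()] result (or a binary matrix).
#' @return a `dist` object.
#' @export
jaccard_matrix <- function(occ) {
  m <- if (is.matrix(occ)) occ else occ_binary(occ)
  if (any(rowSums(m) == 0)) abort("all-zero row in occurrence matrix")
  dist(m, method = "binary")
}

perm_result <- function(method, statistic, stat_name, r2, p, n_perm, seed,
                        extra = list()) {
  structure(c(list(method = method, statistic = statistic,
                   stat_name = stat_name, r2 = r2, p = p,
                   n_perm = n_perm, seed = seed), extra),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test>", x$method, ":", x$stat_name, "=",
      signif(x$statistic, 4),
      if (!is.null(x$r2) && !is.na(x$r2)) paste0("R2 = ", signif(x$r2, 4)),
      " p =", signif(x$p, 4), paste0("(", x$n_perm, " permutations)"), "\n")
  invisible(x)
}

#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, stat_name = x$stat_name,
         r2 = x$r2 %||% NA_real_, p.value = x$p, n_perm = x$n_perm)
}

check_groups <- function(groups, n) {
  groups <- as.factor(groups)
  if (length(groups) != n) abort("groups length must match distance matrix")
  if (nlevels(droplevels(groups)) < 2) abort("need at least 2 groups")
  if (any(table(groups) < 2)) abort("every group needs at least 2 members")
  droplevels(groups)
}

# All distinct assignments of n items to groups of the given sizes, as a
# matrix of level indices (columns = assignments). Used by exact mode and by
# the enumeration oracle in tests.
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  if (n > 10) abort("exact enumeration limited to n <= 10")
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, nrow = length(v)))
    out <- NULL
    for (i in seq_along(v)) {
      rest <- perms(v[-i])
      out <- cbind(out, rbind(v[i], rest))
    }
    out
  }
  all_perm <- perms(seq_len(n))
  labels <- rep(seq_along(sizes), sizes)
  assign <- apply(all_perm, 2, function(ord) labels[order(ord)])
  unique(t(assign))  # rows = distinct assignments (weighted naturally)
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  k <- nlevels(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  f <- ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
  list(f = f, r2 = 1 - ss_within / ss_total)
}

#' PERMANOVA on a distance matrix
#'
#' Pseudo-F from total and within-group sums of squared distances, with a
#' free-permutation p-value. With `exact = TRUE` all distinct label
#' assignments are enumerated (n <= 10) and the p-value is the exact
#' proportion of assignments with F at least the observed one.
#'
#' @param d a `dist` object or symmetric matrix.
#' @param groups group labels, one per observation.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate all assignments instead of sampling.
#' @return a `perm_test` with pseudo-F, R2 and p.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1, exact = FALSE) {
  dm <- as.matrix(d)
  groups <- check_groups(groups, nrow(dm))
  if (!exact && n_perm < 1) abort("n_perm must be >= 1")
  d2 <- dm^2
  obs <- permanova_f(d2, groups)
  if (exact) {
    assigns <- enumerate_assignments(as.integer(table(groups)))
    fs <- apply(assigns, 1, function(a) {
      permanova_f(d2, factor(a))$f
    })
    p <- mean(fs >= obs$f - 1e-12)
    n_perm <- nrow(assigns)
  } else {
    count <- with_seed(seed, {
      cnt <- 0
      for (b in seq_len(n_perm)) {
        fp <- permanova_f(d2, sample(groups))$f
        if (fp >= obs$f - 1e-12) cnt <- cnt + 1
      }
      cnt
    })
    p <- (1 + count) / (1 + n_perm)
  }
  perm_result("PERMANOVA", obs$f, "pseudo-F", obs$r2, p, n_perm, seed)
}

anosim_r <- function(rk, groups, within_mask) {
  mean_b <- mean(rk[!within_mask])
  mean_w <- mean(rk[within_mask])
  n <- length(groups)
  (mean_b - mean_w) / (n * (n - 1) / 4)
}

#' ANOSIM on a distance matrix
#'
#' Rank-based statistic `R = (mean between-group rank - mean within-group
#' rank) / (M/2)` with `M = n(n-1)/2`, free-permutation p-value; `exact`
#' mode as in [permanova()].
#'
#' @inheritParams permanova
#' @return a `perm_test` with R and p.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = 1, exact = FALSE) {
  dm <- as.matrix(d)
  groups <- check_groups(groups, nrow(dm))
  if (!exact && n_perm < 1) abort("n_perm must be >= 1")
  ut <- upper.tri(dm)
  rk_vec <- rank(dm[ut])
  rk <- matrix(0, nrow(dm), ncol(dm))
  rk[ut] <- rk_vec
  rk <- rk + t(rk)
  pair_rank <- rk[ut]
  within_of <- function(g) {
    gm <- outer(g, g, "==")
    gm[ut]
  }
  obs <- anosim_r(pair_rank, groups, within_of(groups))
  if (exact) {
    assigns <- enumerate_assignments(as.integer(table(groups)))
    rs <- apply(assigns, 1, function(a) {
      anosim_r(pair_rank, a, within_of(a))
    })
    p <- mean(rs >= obs - 1e-12)
    n_perm <- nrow(assigns)
  } else {
    count <- with_seed(seed, {
      cnt <- 0
      for (b in seq_len(n_perm)) {
        g <- sample(groups)
        if (anosim_r(pair_rank, g, within_of(g)) >= obs - 1e-12) cnt <- cnt + 1
      }
      cnt
    })
    p <- (1 + count) / (1 + n_perm)
  }
  perm_result("ANOSIM", obs, "R", NULL, p, n_perm, seed)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-d^2/2` followed by an eigendecomposition.
#' Negative eigenvalues (non-Euclidean distances such as Jaccard) are kept:
#' `points` holds axes for positive eigenvalues, `imaginary` the axes for
#' negative ones (scaled by `sqrt(-lambda)`), as needed for Anderson's
#' dispersion correction.
#'
#' @param d a `dist` or symmetric matrix.
#' @param eps eigenvalue magnitude below which axes are dropped as null.
#' @return list with `points`, `imaginary`, `eigenvalues`.
#' @export
pcoa <- function(d, eps = 1e-9) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  a <- -dm^2 / 2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  eg <- eigen(g, symmetric = TRUE)
  lambda <- eg$values
  scale_axes <- function(idx, sign) {
    if (!length(idx)) return(matrix(0, n, 0))
    sweep(eg$vectors[, idx, drop = FALSE], 2, sqrt(sign * lambda[idx]), "*")
  }
  tol <- eps * max(abs(lambda), 1)
  pos <- which(lambda > tol)
  neg <- which(lambda < -tol)
  pts <- scale_axes(pos, 1)
  im <- scale_axes(neg, -1)
  rownames(pts) <- rownames(im) <- rownames(dm)
  list(points = pts, imaginary = im, eigenvalues = lambda)
}

disp_distances <- function(pc, groups) {
  # Distance of each observation to its group centroid, with the
  # imaginary-axis correction sqrt(max(0, |re|^2 - |im|^2)).
  z <- numeric(length(groups))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    cr <- colMeans(pc$points[idx, , drop = FALSE])
    ci <- colMeans(pc$imaginary[idx, , drop = FALSE])
    re2 <- rowSums(sweep(pc$points[idx, , drop = FALSE], 2, cr)^2)
    im2 <- rowSums(sweep(pc$imaginary[idx, , drop = FALSE], 2, ci)^2)
    z[idx] <- sqrt(pmax(0, re2 - im2))
  }
  z
}

anova_f <- function(z, groups) {
  n <- length(z); k <- nlevels(groups)
  gm <- tapply(z, groups, mean)
  ss_b <- sum(tapply(z, groups, length) * (gm - mean(z))^2)
  ss_w <- sum((z - gm[groups])^2)
  if (ss_w <= 0) return(if (ss_b <= 0) 0 else Inf)
  (ss_b / (k - 1)) / (ss_w / (n - k))
}

#' Homogeneity of multivariate dispersion
#'
#' Per-observation distances to group centroids in PCoA space (with the
#' imaginary-axis correction for non-Euclidean distances), compared across
#' groups by a one-way F statistic with a label-permutation p-value
#' (distances are recomputed under each relabelling).
#'
#' @inheritParams permanova
#' @return a `perm_test` with F, p, and per-observation `distances`.
#' @export
dispersion_test <- function(d, groups, n_perm = 999, seed = 1) {
  dm <- as.matrix(d)
  groups <- check_groups(groups, nrow(dm))
  if (n_perm < 1) abort("n_perm must be >= 1")
  pc <- pcoa(d)
  z_obs <- disp_distances(pc, groups)
  f_obs <- anova_f(z_obs, groups)
  count <- with_seed(seed, {
    cnt <- 0
    for (b in seq_len(n_perm)) {
      g <- sample(groups)
      if (anova_f(disp_distances(pc, g), g) >= f_obs - 1e-12) cnt <- cnt + 1
    }
    cnt
  })
  perm_result("dispersion", f_obs, "F", NULL, (1 + count) / (1 + n_perm),
              n_perm, seed, extra = list(distances = z_obs))
}

dbrda_f <- function(y, x_factor) {
  x <- model.matrix(~x_factor)
  qr_x <- qr(x)
  fitted <- qr.fitted(qr_x, y)
  yc <- sweep(y, 2, colMeans(y))
  fc <- sweep(fitted, 2, colMeans(fitted))
  ss_exp <- sum(fc^2)
  ss_tot <- sum(yc^2)
  ss_res <- ss_tot - ss_exp
  k <- nlevels(x_factor)
  n <- nrow(y)
  list(f = (ss_exp / (k - 1)) / (ss_res / (n - k)), r2 = ss_exp / ss_tot)
}

#' Distance-based redundancy analysis
#'
#' Regresses the positive-eigenvalue PCoA coordinates on group indicators
#' (no Lingoes/Cailliez correction — a documented dialect choice) and tests
#' the constrained variance fraction by label permutation.
#'
#' @inheritParams permanova
#' @return a `perm_test` with F, R2 and p.
#' @export
dbrda <- function(d, groups, n_perm = 999, seed = 1) {
  dm <- as.matrix(d)
  groups <- check_groups(groups, nrow(dm))
  if (n_perm < 1) abort("n_perm must be >= 1")
  y <- pcoa(d)$points
  obs <- dbrda_f(y, groups)
  count <- with_seed(seed, {
    cnt <- 0
    for (b in seq_len(n_perm)) {
      if (dbrda_f(y, sample(groups))$f >= obs$f - 1e-12) cnt <- cnt + 1
    }
    cnt
  })
  perm_result("db-RDA", obs$f, "F", obs$r2, (1 + count) / (1 + n_perm),
              n_perm, seed)
}

stress1 <- function(conf_d, dhat) {
  sqrt(sum((conf_d - dhat)^2) / sum(conf_d^2))
}

# Linear-time pool-adjacent-violators: merge decreasing neighbours into
# weighted blocks kept on a stack.
pava <- function(y) {
  n <- length(y)
  means <- numeric(n); sizes <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    means[top] <- y[i]; sizes[top] <- 1L
    while (top > 1L && means[top - 1L] > means[top]) {
      w <- sizes[top - 1L] + sizes[top]
      means[top - 1L] <- (means[top - 1L] * sizes[top - 1L] +
                            means[top] * sizes[top]) / w
      sizes[top - 1L] <- w
      top <- top - 1L
    }
  }
  rep.int(means[seq_len(top)], sizes[seq_len(top)])
}

# Monotone regression of configuration distances on the dissimilarity order,
# Kruskal's primary approach to ties (tie groups pre-sorted by distance).
monotone_fit <- function(conf_d, ord) {
  fit <- numeric(length(conf_d))
  fit[ord] <- pava(conf_d[ord])
  fit
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimized by alternating pool-adjacent-violators monotone
#' regression with Guttman-transform configuration updates, best of
#' `n_restarts` (first start from PCoA, the rest random).
#'
#' @param d a `dist` or symmetric matrix.
#' @param k target dimensionality (>= 1).
#' @param seed integer seed.
#' @param n_restarts number of starts.
#' @param max_iter,tol iteration cap and relative stress-improvement cutoff.
#' @return list with `points` (n x k), `stress`, and `trace` (stress per
#'   iteration of the winning start, non-increasing).
#' @export
nmds <- function(d, k = 2, seed = 1, n_restarts = 4, max_iter = 200,
                 tol = 1e-7) {
  if (k < 1) abort("k must be >= 1")
  dm <- as.matrix(d)
  n <- nrow(dm)
  ut <- upper.tri(dm)
  delta <- dm[ut]
  idx <- which(ut, arr.ind = TRUE)
  best <- NULL
  with_seed(seed, for (r in seq_len(n_restarts)) {
    x <- if (r == 1) {
      p <- pcoa(dm)$points
      if (ncol(p) >= k) p[, 1:k, drop = FALSE] else
        cbind(p, matrix(rnorm(n * (k - ncol(p)), 0, 1e-3), n))
    } else {
      matrix(rnorm(n * k), n, k)
    }
    trace <- numeric(0)
    s_prev <- Inf
    for (it in seq_len(max_iter)) {
      conf_d <- sqrt(rowSums((x[idx[, 1], , drop = FALSE] -
                              x[idx[, 2], , drop = FALSE])^2))
      ord_it <- order(delta, conf_d)
      dhat <- monotone_fit(conf_d, ord_it)
      s <- stress1(conf_d, dhat)
      trace <- c(trace, s)
      if (!is.finite(s) || s < 1e-12 || (s_prev - s) < tol * s_prev) break
      s_prev <- s
      # Guttman transform with target dhat
      ratio <- ifelse(conf_d > 1e-12, dhat / conf_d, 0)
      b <- matrix(0, n, n)
      b[ut] <- -ratio
      b <- b + t(b)
      diag(b) <- -rowSums(b)
      x <- b %*% x / n
    }
    if (is.null(best) || utils::tail(trace, 1) < best$stress) {
      best <- list(points = x, stress = utils::tail(trace, 1), trace = trace)
    }
  })
  rownames(best$points) <- rownames(dm)
  best
}

#' Run the full suite of community tests on a collection
#'
#' Builds the occurrence matrix, computes Jaccard distances, and applies
#' PERMANOVA, ANOSIM, the dispersion test, and db-RDA to both groupings the
#' design compares — continent and assignment type — plus an NMDS ordination.
#'
#' @param collection an `edna_collection`.
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @param k NMDS dimensionality.
#' @return list with `tests` (tidy tibble over all tests), `nmds`
#'   (coordinates tibble with metadata), `occurrence`, and the `dist` object.
#' @export
community_tests <- function(collection, n_perm = 999, seed = 1, k = 2) {
  occ <- build_occurrence_matrix(collection)
  d <- jaccard_matrix(occ)
  run_all <- function(groups, label) {
    list(
      permanova = permanova(d, groups, n_perm, seed),
      anosim = anosim(d, groups, n_perm, seed),
      dispersion = dispersion_test(d, groups, n_perm, seed),
      dbrda = dbrda(d, groups, n_perm, seed)
    ) %>%
      map(tidy) %>%
      bind_rows() %>%
      mutate(grouping = label, .before = 1)
  }
  tests <- bind_rows(run_all(occ$continent, "continent"),
                     run_all(occ$assignment_type, "assignment_type"))
  mds <- nmds(d, k = k, seed = seed)
  coords <- as_tibble(mds$points, .name_repair = ~ paste0("axis", seq_len(k)))
  nm <- dplyr::bind_cols(
    occ[, attr(occ, "meta_cols"), drop = FALSE], coords
  ) %>% mutate(stress = mds$stress)
  list(tests = tests, nmds = nm, occurrence = occ, dist = d)
}

#' Plot an NMDS ordination
#' @param nmds_tbl the `nmds` tibble from [community_tests()].
#' @return a ggplot.
#' @export
plot_nmds <- function(nmds_tbl) {
  ggplot2::ggplot(nmds_tbl,
                  ggplot2::aes(x = .data$axis1, y = .data$axis2,
                               colour = .data$continent,
                               shape = .data$assignment_type)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      subtitle = sprintf("stress = %.3f", nmds_tbl$stress[1])
    ) +
    ggplot2::theme_bw()
}
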