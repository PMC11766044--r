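## Independent brute-force oracles and small fixture factories used across
## the test files. Oracles deliberately use naive, loop-based code paths.

`%||%` <- function(x, y) if (is.null(x)) y else x

## -- tiny genome/design factories ------------------------------------------

tiny_genome <- function(n_loci = 50, len = 1e6, causal_pos = 5e5,
                        recomb_rate = 1.6e-8) {
  genome_spec(data.frame(name = "c1", length = len), n_loci,
              recomb_rate = recomb_rate,
              causal = list(chrom = "c1", pos = causal_pos))
}

two_chrom_genome <- function(n_loci = 50) {
  genome_spec(data.frame(name = c("c1", "c2"), length = c(1e6, 1e6)),
              n_loci, causal = list(chrom = "c1", pos = 5e5))
}

## -- LOESS oracle: per-point weighted least squares via lm() ---------------

loess_oracle <- function(positions, values, span = 0.1) {
  n <- length(positions)
  ord <- order(positions)
  x <- as.numeric(positions[ord])
  y <- as.numeric(values[ord])
  q <- max(3L, min(n, as.integer(ceiling(span * n))))
  fitted_sorted <- sapply(seq_len(n), function(i) {
    ## expand outward to the q nearest neighbours, preferring left on ties
    lo <- i
    hi <- i
    while (hi - lo + 1L < q) {
      if (lo == 1L) {
        hi <- hi + 1L
      } else if (hi == n) {
        lo <- lo - 1L
      } else if (x[i] - x[lo - 1L] <= x[hi + 1L] - x[i]) {
        lo <- lo - 1L
      } else {
        hi <- hi + 1L
      }
    }
    idx <- lo:hi
    d <- abs(x[idx] - x[i])
    dmax <- max(d)
    if (dmax == 0) return(mean(y[idx]))
    w <- (1 - (d / dmax)^3)^3
    xc <- x[idx] - x[i]
    keep <- w > 0
    if (length(unique(x[idx][keep])) < 2) {
      return(sum(w * y[idx]) / sum(w))
    }
    fit <- stats::lm(yy ~ xc, data = data.frame(yy = y[idx], xc = xc),
                     weights = w)
    unname(stats::coef(fit)[1])
  })
  out <- numeric(n)
  out[ord] <- fitted_sorted
  out
}

## -- PLS1 / VIP oracle: explicit loops, no matrix shortcuts ----------------

pls_vip_oracle <- function(X, y, n_components = 2) {
  n <- nrow(X)
  J <- ncol(X)
  ## autoscale by hand
  E <- X
  for (j in seq_len(J)) {
    E[, j] <- (X[, j] - mean(X[, j])) / stats::sd(X[, j])
  }
  f <- y - mean(y)
  W <- matrix(0, J, n_components)
  ssy <- numeric(n_components)
  scores <- matrix(0, n, n_components)
  for (a in seq_len(n_components)) {
    w <- sapply(seq_len(J), function(j) sum(E[, j] * f))  # X'f per column
    w <- w / sqrt(sum(w^2))
    tt <- numeric(n)
    for (i in seq_len(n)) tt[i] <- sum(E[i, ] * w)
    tss <- sum(tt^2)
    p <- sapply(seq_len(J), function(j) sum(E[, j] * tt) / tss)
    q <- sum(f * tt) / tss
    for (i in seq_len(n)) for (j in seq_len(J)) E[i, j] <- E[i, j] - tt[i] * p[j]
    f <- f - q * tt
    W[, a] <- w
    ssy[a] <- q^2 * tss
    scores[, a] <- tt
  }
  vip <- sapply(seq_len(J), function(j) {
    num <- 0
    for (a in seq_len(n_components)) {
      num <- num + ssy[a] * (W[j, a]^2 / sum(W[, a]^2))
    }
    sqrt(J * num / sum(ssy))
  })
  list(vip = vip, weights = W, ssy = ssy, scores = scores)
}

## long lipid tibble from a plain matrix (species x samples, 4 + 4 design)
lipid_ds_from_matrix <- function(mat, species = NULL) {
  n_rep <- ncol(mat) / 2
  species <- species %||% paste0("SP", seq_len(nrow(mat)), "(36:2)")
  groups <- rep(c("WT", "mutant"), each = n_rep)
  samples <- paste0(ifelse(groups == "WT", "WT_", "mut_"),
                    rep(seq_len(n_rep), 2))
  out <- list()
  for (i in seq_len(nrow(mat))) {
    out[[i]] <- tibble::tibble(
      species = species[i], sample = samples, group = groups,
      replicate = rep(seq_len(n_rep), 2), intensity = mat[i, ])
  }
  ds <- dplyr::bind_rows(out)
  dplyr::left_join(ds, parse_lipid_name(unique(ds$species)),
                   by = c(species = "name"))
}

## -- fine-mapping bin-enumeration oracle -----------------------------------

## feasibility of every bin (marker, gap, marker, ...) for all sterile
## plants, by direct enumeration
finemap_oracle_bins <- function(markers, genotypes) {
  k <- nrow(markers)
  geno <- as.matrix(genotypes[markers$marker])
  sterile <- which(genotypes$phenotype == "sterile")
  n_bins <- 2L * k - 1L
  feas <- rep(TRUE, n_bins)
  for (b in seq_len(n_bins)) {
    for (pidx in sterile) {
      g <- geno[pidx, ]
      compatible <- g %in% c("M", "?")
      ok <- if (b %% 2L == 1L) {
        compatible[(b + 1L) %/% 2L]
      } else {
        compatible[b %/% 2L] || compatible[b %/% 2L + 1L]
      }
      if (!ok) {
        feas[b] <- FALSE
        break
      }
    }
  }
  feas
}

## random recombinant table; sterile genotypes are built as M-runs that all
## cover a common bin, so most tables are consistent; with prob noise_p a
## sterile plant gets a disruptive non-M genotype to exercise the
## inconsistent path
random_recombinant_table <- function(k = NULL, n_sterile = NULL,
                                     n_fertile = NULL, noise_p = 0.1,
                                     wildcard_p = 0.1) {
  k <- k %||% sample(3:8, 1)
  n_sterile <- n_sterile %||% sample(1:5, 1)
  n_fertile <- n_fertile %||% sample(0:3, 1)
  markers <- tibble::tibble(
    marker = paste0("m", seq_len(k)), chrom = "chr5",
    pos = sort(sample.int(5e6, k)))
  common <- sample.int(k, 1)
  plants <- list()
  for (s in seq_len(n_sterile)) {
    a <- sample.int(common, 1)
    b <- common + sample.int(k - common + 1L, 1) - 1L
    g <- rep("H", k)
    g[a:b] <- "M"
    out_run <- setdiff(seq_len(k), a:b)
    g[out_run] <- sample(c("H", "B"), length(out_run), replace = TRUE)
    g[runif(k) < wildcard_p] <- "?"
    if (runif(1) < noise_p) g[sample.int(k, 1)] <- sample(c("H", "B"), 1)
    plants[[length(plants) + 1L]] <-
      c(plant = paste0("S", s), phenotype = "sterile", setNames(g, markers$marker))
  }
  for (f in seq_len(n_fertile)) {
    g <- sample(c("M", "H", "B", "?"), k, replace = TRUE,
                prob = c(0.2, 0.4, 0.3, 0.1))
    plants[[length(plants) + 1L]] <-
      c(plant = paste0("F", f), phenotype = "fertile", setNames(g, markers$marker))
  }
  genotypes <- dplyr::bind_rows(lapply(plants, function(p) {
    tibble::as_tibble(as.list(p))
  }))
  list(markers = markers, genotypes = genotypes)
}

## path to a shipped fixture
fixture <- function(name) {
  system.file("extdata", name, package = "msmapr", mustWork = TRUE)
}
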