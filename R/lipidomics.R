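#' Parse lipid shorthand names
#'
#' Parses names of the form `SUBCLASS(C:D)` — e.g. `PC(36:4)` — where `C` is
#' the total acyl carbon count and `D` the number of double bonds. Optional
#' ether/plasmalogen prefixes inside the parentheses (`O-`, `P-`, `d`, `t`)
#' and trailing modifiers (adducts, `_k` de-duplication suffixes) are
#' tolerated. Names without a `(C:D)` group get `parse_ok = FALSE`; they are
#' excluded from chain-length/saturation profiles only, never from intensity
#' statistics.
#'
#' @param name Character vector of lipid names.
#' @return Tibble: `name`, `subclass`, `carbons`, `double_bonds`, `parse_ok`.
#' @examples
#' parse_lipid_name(c("PC(36:4)", "TG(52:3)", "Cholesterol"))
#' @export
parse_lipid_name <- function(name) {
  pattern <- "^\\s*([A-Za-z0-9]+)\\s*\\((?:[OPdt]-?)?(\\d+):(\\d+)[^)]*\\)"
  m <- regexec(pattern, name)
  parts <- regmatches(name, m)
  out <- purrr::map_dfr(seq_along(name), function(i) {
    p <- parts[[i]]
    if (length(p) == 4L) {
      tibble(name = name[i], subclass = p[2],
             carbons = as.integer(p[3]), double_bonds = as.integer(p[4]),
             parse_ok = TRUE)
    } else {
      tibble(name = name[i], subclass = NA_character_,
             carbons = NA_integer_, double_bonds = NA_integer_,
             parse_ok = FALSE)
    }
  })
  out
}

## validate / normalize a long-format lipid dataset
check_lipidome <- function(ds) {
  ds <- as_tibble(ds)
  need <- c("species", "sample", "group", "intensity")
  if (!all(need %in% names(ds))) {
    abort(sprintf("lipid dataset needs columns %s", toString(need)))
  }
  if (!all(ds$group %in% c("WT", "mutant"))) {
    abort("`group` must be 'WT' or 'mutant'")
  }
  if (any(ds$intensity < 0, na.rm = TRUE)) abort("negative intensities")
  reps <- dplyr::distinct(ds, .data$sample, .data$group) |>
    dplyr::count(.data$group)
  if (nrow(reps) < 2 || any(reps$n < 2)) {
    abort("need >= 2 replicates in each of the two groups")
  }
  if (!"subclass" %in% names(ds)) {
    ds <- dplyr::left_join(
      ds, parse_lipid_name(unique(ds$species)),
      by = c(species = "name"))
  }
  ds
}

#' Total lipid content per group and mutant/WT ratio
#'
#' Group total = sum of every species intensity over all replicates of the
#' group; the ratio is `100 * total_mutant / total_WT`. With equal replicate
#' counts this equals the ratio of group means.
#'
#' @param ds Long-format lipid dataset (see [simulate_lipidome()]): columns
#'   `species`, `sample`, `group` (`"WT"`/`"mutant"`), `intensity`.
#' @return One-row tibble: `total_wt`, `total_mutant`, `ratio_pct`
#'   (1 decimal place), `ratio` (full precision).
#' @examples
#' total_content(simulate_lipidome(lipidome_spec(seed = 1)))
#' @export
total_content <- function(ds) {
  ds <- check_lipidome(ds)
  tot <- dplyr::summarise(dplyr::group_by(ds, .data$group),
                          total = sum(.data$intensity), .groups = "drop")
  total_wt <- tot$total[tot$group == "WT"]
  total_mut <- tot$total[tot$group == "mutant"]
  if (total_wt == 0) abort("WT total intensity is zero")
  ratio <- 100 * total_mut / total_wt
  tibble(total_wt = total_wt, total_mutant = total_mut,
         ratio_pct = round(ratio, 1), ratio = ratio)
}

## Welch (or pooled) two-sample t-test p-value with a documented rule for
## degenerate zero-variance inputs: equal constant groups -> p = 1,
## different constant groups -> p = 0
two_group_p <- function(x_wt, x_mut, pooled = FALSE) {
  if (sd(x_wt) == 0 && sd(x_mut) == 0) {
    return(if (mean(x_wt) == mean(x_mut)) 1 else 0)
  }
  tryCatch(
    t.test(x_mut, x_wt, var.equal = pooled)$p.value,
    error = function(e) NA_real_
  )
}

p_tier <- function(p) {
  dplyr::case_when(is.na(p) ~ "ns", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Per-subclass intensity tests
#'
#' For each lipid subclass, the per-replicate subclass intensity is the sum
#' of its member species; groups are compared by a Welch two-sample t-test on
#' those per-replicate sums (set `pooled = TRUE` for the classical
#' equal-variance test, which with two groups coincides with one-way ANOVA).
#' Tiers mark `p < 0.05` (`*`) and `p < 0.01` (`**`).
#'
#' @inheritParams total_content
#' @param pooled Use the pooled-variance t-test instead of Welch
#'   (default `FALSE`).
#' @param log_transform Test log10 intensities instead of raw (default
#'   `FALSE`, mirroring intensity-scale group comparisons).
#' @return Tibble per subclass: `subclass`, `n_species`, `sum_wt`,
#'   `sum_mutant`, `mean_wt`, `mean_mutant`, `log2fc`, `direction`,
#'   `p_value`, `tier`, `degenerate`.
#' @export
subclass_tests <- function(ds, pooled = FALSE, log_transform = FALSE) {
  ds <- check_lipidome(ds)
  per_rep <- dplyr::summarise(
    dplyr::group_by(ds, .data$subclass, .data$group, .data$sample),
    value = sum(.data$intensity), n_species = dplyr::n_distinct(.data$species),
    .groups = "drop")
  if (log_transform) per_rep$value <- log10(per_rep$value)
  out <- per_rep |>
    dplyr::group_by(.data$subclass) |>
    dplyr::summarise(
      n_species = max(.data$n_species),
      sum_wt = sum(.data$value[.data$group == "WT"]),
      sum_mutant = sum(.data$value[.data$group == "mutant"]),
      mean_wt = mean(.data$value[.data$group == "WT"]),
      mean_mutant = mean(.data$value[.data$group == "mutant"]),
      p_value = two_group_p(.data$value[.data$group == "WT"],
                            .data$value[.data$group == "mutant"],
                            pooled = pooled),
      degenerate = sd(.data$value[.data$group == "WT"]) == 0 &&
        sd(.data$value[.data$group == "mutant"]) == 0,
      .groups = "drop")
  out$log2fc <- log2(out$mean_mutant / out$mean_wt)
  out$direction <- ifelse(out$mean_mutant >= out$mean_wt, "up", "down")
  out$tier <- p_tier(out$p_value)
  dplyr::select(out, "subclass", "n_species", "sum_wt", "sum_mutant",
                "mean_wt", "mean_mutant", "log2fc", "direction", "p_value",
                "tier", "degenerate")
}

#' Fit a two-class PLS-DA model
#'
#' Partial-least-squares discriminant analysis for the two-group design:
#' the class is coded +1 (mutant) / -1 (WT), species intensities are
#' autoscaled (zero mean, unit variance per species), and components are
#' extracted iteratively (NIPALS for a single response: weight vector
#' `w = X'y / |X'y|`, score `t = X w`, loading `p = X't / t't`, response
#' loading `q = y't / t't`, then deflation of X). Zero-variance species are
#' removed before the fit (their VIP is reported as 0, with a warning).
#'
#' @inheritParams total_content
#' @param n_components Number of latent components (default 2). Requests
#'   beyond the data's rank are truncated with a warning.
#' @return Object of class `plsda_fit`: `weights`, `scores`, `loadings`,
#'   `q`, `ssy` (response variance explained per component), `vip` (named
#'   vector over all species, 0 for zero-variance ones), `species`,
#'   `n_components`, `r2y`.
#' @export
plsda_fit <- function(ds, n_components = 2) {
  ds <- check_lipidome(ds)
  assert_count(n_components, "n_components", lower = 1)
  wide <- tidyr::pivot_wider(
    dplyr::distinct(ds, .data$species, .data$sample, .data$group,
                    .data$intensity),
    names_from = "species", values_from = "intensity")
  X <- as.matrix(wide[, setdiff(names(wide), c("sample", "group"))])
  rownames(X) <- wide$sample
  y <- ifelse(wide$group == "mutant", 1, -1)
  if (nrow(X) < 3) abort("need >= 3 samples for a PLS-DA fit")
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warn(sprintf("%d zero-variance species removed from the PLS-DA fit (VIP = 0)",
                 length(dropped)))
  }
  keep <- colnames(X)[sds > 0]
  Xa <- scale(X[, keep, drop = FALSE])
  yc <- y - mean(y)
  amax <- min(n_components, nrow(Xa) - 1L, length(keep))
  if (amax < n_components) {
    warn(sprintf("n_components truncated from %d to %d (rank limit)",
                 n_components, amax))
  }
  J <- length(keep)
  W <- matrix(0, J, amax, dimnames = list(keep, NULL))
  Tm <- matrix(0, nrow(Xa), amax)
  P <- matrix(0, J, amax)
  qv <- numeric(amax)
  ssy <- numeric(amax)
  E <- Xa
  f <- yc
  a_used <- 0L
  for (a in seq_len(amax)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- drop(E %*% w)
    tss <- sum(tt^2)
    if (tss < 1e-12) break
    p <- drop(crossprod(E, tt)) / tss
    q <- sum(f * tt) / tss
    W[, a] <- w
    Tm[, a] <- tt
    P[, a] <- p
    qv[a] <- q
    ssy[a] <- q^2 * tss
    E <- E - tcrossprod(tt, p)
    f <- f - q * tt
    a_used <- a
  }
  if (a_used < amax) {
    W <- W[, seq_len(a_used), drop = FALSE]
    Tm <- Tm[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    qv <- qv[seq_len(a_used)]
    ssy <- ssy[seq_len(a_used)]
  }
  ## VIP_j = sqrt( J * sum_a ssy_a (w_aj / |w_a|)^2 / sum_a ssy_a )
  wnorm2 <- colSums(W^2)
  contrib <- sweep(W^2, 2, ifelse(wnorm2 > 0, wnorm2, 1), "/")
  vip_kept <- sqrt(J * drop(contrib %*% ssy) / sum(ssy))
  all_species <- colnames(X)
  vip <- setNames(numeric(length(all_species)), all_species)
  vip[keep] <- vip_kept
  structure(
    list(weights = W, scores = Tm, loadings = P, q = qv, ssy = ssy,
         vip = vip, species = all_species, dropped = dropped,
         n_components = a_used, r2y = sum(ssy) / sum(yc^2),
         y = y, samples = wide$sample),
    class = "plsda_fit")
}

#' VIP scores per species
#'
#' Variable importance in projection from a [plsda_fit()]: for species `j`,
#' `VIP_j = sqrt(J * sum_a SSY_a (w_aj/|w_a|)^2 / sum_a SSY_a)` with `J` the
#' species count, `w_a` the component weight vectors and `SSY_a` the response
#' variance explained by component `a`. Mean squared VIP over species is 1 by
#' construction, so VIP > 1 marks above-average discriminating species.
#'
#' @inheritParams plsda_fit
#' @return Tibble `species`, `vip`.
#' @export
plsda_vip <- function(ds, n_components = 2) {
  fit <- plsda_fit(ds, n_components = n_components)
  tibble(species = fit$species, vip = unname(fit$vip[fit$species]))
}

#' @export
tidy.plsda_fit <- function(x, ...) {
  tb <- tibble(species = x$species, vip = unname(x$vip[x$species]))
  for (a in seq_len(x$n_components)) {
    wa <- setNames(numeric(length(x$species)), x$species)
    wa[rownames(x$weights)] <- x$weights[, a]
    tb[[paste0("weight_", a)]] <- unname(wa[x$species])
  }
  tb
}

#' @export
glance.plsda_fit <- function(x, ...) {
  tibble(n_components = x$n_components, r2y = x$r2y,
         n_species = length(x$species),
         n_dropped = length(x$dropped))
}

#' Differential lipid species (VIP > 1 and p < 0.05)
#'
#' Computes per-species Welch t-tests and PLS-DA VIP scores and applies the
#' conventional joint screen: a species is differential iff
#' `vip > vip_threshold` and `p_value < p_threshold`. Direction is the sign
#' of the mutant-vs-WT log2 fold-change of group means, so the up and down
#' counts always partition the differential set.
#'
#' @inheritParams plsda_fit
#' @param vip_threshold VIP cutoff (default 1).
#' @param p_threshold p-value cutoff (default 0.05).
#' @param pooled,log_transform Passed to the per-species t-tests (see
#'   [subclass_tests()]).
#' @param fdr Apply Benjamini-Hochberg correction to the p-values before
#'   thresholding (default `FALSE`, mirroring a raw-p screen).
#' @return Tibble of class `lipid_diff`, one row per species: `species`,
#'   `subclass`, `mean_wt`, `mean_mutant`, `log2fc`, `p_value`, `vip`,
#'   `is_differential`, `direction`. Attribute `counts` holds
#'   `n_differential`, `n_up`, `n_down`.
#' @examples
#' diff <- differential_species(simulate_lipidome(lipidome_spec(seed = 1)))
#' glance(diff)
#' @export
differential_species <- function(ds, vip_threshold = 1, p_threshold = 0.05,
                                 n_components = 2, pooled = FALSE,
                                 log_transform = FALSE, fdr = FALSE) {
  ds <- check_lipidome(ds)
  vips <- plsda_vip(ds, n_components = n_components)
  val <- ds
  if (log_transform) val$intensity <- log10(val$intensity)
  stats_tb <- val |>
    dplyr::group_by(.data$species, .data$subclass) |>
    dplyr::summarise(
      mean_wt = mean(.data$intensity[.data$group == "WT"]),
      mean_mutant = mean(.data$intensity[.data$group == "mutant"]),
      p_value = two_group_p(.data$intensity[.data$group == "WT"],
                            .data$intensity[.data$group == "mutant"],
                            pooled = pooled),
      .groups = "drop")
  if (fdr) stats_tb$p_value <- stats::p.adjust(stats_tb$p_value, "BH")
  out <- dplyr::left_join(stats_tb, vips, by = "species")
  out$log2fc <- log2(out$mean_mutant / out$mean_wt)
  out$is_differential <- !is.na(out$p_value) & !is.na(out$vip) &
    out$vip > vip_threshold & out$p_value < p_threshold
  out$direction <- ifelse(out$mean_mutant >= out$mean_wt, "up", "down")
  out <- dplyr::select(out, "species", "subclass", "mean_wt", "mean_mutant",
                       "log2fc", "p_value", "vip", "is_differential",
                       "direction")
  counts <- list(
    n_differential = sum(out$is_differential),
    n_up = sum(out$is_differential & out$direction == "up"),
    n_down = sum(out$is_differential & out$direction == "down"))
  structure(out, counts = counts, class = c("lipid_diff", class(out)))
}

#' @export
glance.lipid_diff <- function(x, ...) {
  cts <- attr(x, "counts")
  tibble(n_species = nrow(x), n_differential = cts$n_differential,
         n_up = cts$n_up, n_down = cts$n_down)
}

#' Chain-length and saturation profiles
#'
#' For the subclasses of interest, parseable species are binned by total acyl
#' carbons (chain length) and, separately, by double-bond count
#' (saturation). Per subclass and bin, per-replicate intensities are summed
#' and the groups compared by a Welch t-test. Unparseable species never
#' contribute; empty bins are omitted.
#'
#' @inheritParams subclass_tests
#' @param subclasses Subclasses profiled (default the four dominant membrane
#'   classes `PE`, `PC`, `DG`, `MGDG`).
#' @return Tibble: `subclass`, `dimension` (`"chain_length"` or
#'   `"saturation"`), `bin`, `n_species`, `mean_wt`, `mean_mutant`,
#'   `log2fc`, `p_value`, `tier`.
#' @export
chain_profiles <- function(ds, subclasses = c("PE", "PC", "DG", "MGDG"),
                           pooled = FALSE) {
  ds <- check_lipidome(ds)
  if (!all(c("carbons", "double_bonds") %in% names(ds))) {
    parsed <- parse_lipid_name(unique(ds$species))
    ds <- dplyr::left_join(dplyr::select(ds, -dplyr::any_of("subclass")),
                           parsed, by = c(species = "name"))
  }
  keep <- ds$subclass %in% subclasses &
    !is.na(ds$carbons) & !is.na(ds$double_bonds)
  sub <- ds[keep, ]
  if (nrow(sub) == 0) {
    return(tibble(subclass = character(), dimension = character(),
                  bin = integer(), n_species = integer(),
                  mean_wt = numeric(), mean_mutant = numeric(),
                  log2fc = numeric(), p_value = numeric(),
                  tier = character()))
  }
  profile_one <- function(data, var, label) {
    per_rep <- data |>
      dplyr::group_by(.data$subclass, bin = .data[[var]], .data$group,
                      .data$sample) |>
      dplyr::summarise(value = sum(.data$intensity),
                       n_species = dplyr::n_distinct(.data$species),
                       .groups = "drop")
    per_rep |>
      dplyr::group_by(.data$subclass, .data$bin) |>
      dplyr::summarise(
        n_species = max(.data$n_species),
        mean_wt = mean(.data$value[.data$group == "WT"]),
        mean_mutant = mean(.data$value[.data$group == "mutant"]),
        p_value = two_group_p(.data$value[.data$group == "WT"],
                              .data$value[.data$group == "mutant"],
                              pooled = pooled),
        .groups = "drop") |>
      dplyr::mutate(dimension = label,
                    log2fc = log2(.data$mean_mutant / .data$mean_wt),
                    tier = p_tier(.data$p_value))
  }
  out <- dplyr::bind_rows(
    profile_one(sub, "carbons", "chain_length"),
    profile_one(sub, "double_bonds", "saturation"))
  dplyr::select(out, "subclass", "dimension", "bin", "n_species", "mean_wt",
                "mean_mutant", "log2fc", "p_value", "tier")
}

#' Row-standardized intensities and clustering order for a heatmap
#'
#' Standardizes each species row to mean 0 and SD 1 across samples, then
#' clusters species by Euclidean distance with average-linkage agglomeration.
#' Zero-variance rows become rows of zeros and are flagged.
#'
#' @inheritParams total_content
#' @param species Species to include; defaults to all in `ds`. Pass the
#'   differential set from [differential_species()] for the conventional
#'   differential-lipid heatmap.
#' @return List of class `lipid_clust`: `order` (species in dendrogram leaf
#'   order), `hclust` (the merge tree), `z` (tibble of z-scores, species x
#'   sample, in input order), `flagged` (zero-variance species).
#' @export
cluster_heatmap_order <- function(ds, species = NULL) {
  ds <- check_lipidome(ds)
  if (!is.null(species)) ds <- ds[ds$species %in% species, ]
  wide <- tidyr::pivot_wider(
    dplyr::distinct(ds, .data$species, .data$sample, .data$intensity),
    names_from = "sample", values_from = "intensity")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$species
  if (nrow(mat) < 2) abort("need >= 2 species to cluster")
  sds <- apply(mat, 1, sd)
  z <- (mat - rowMeans(mat)) / ifelse(sds > 0, sds, 1)
  z[sds == 0, ] <- 0
  flagged <- rownames(mat)[sds == 0]
  if (length(flagged)) {
    warn(sprintf("%d zero-variance species row(s) set to zero z-scores",
                 length(flagged)))
  }
  hc <- hclust(dist(z, method = "euclidean"), method = "average")
  structure(
    list(order = rownames(mat)[hc$order], hclust = hc,
         z = dplyr::bind_cols(tibble(species = rownames(mat)),
                              as_tibble(z)),
         flagged = flagged),
    class = "lipid_clust")
}

#' @export
print.lipid_clust <- function(x, ...) {
  cat(sprintf("<lipid_clust> %d species, average linkage; first leaves: %s\n",
              length(x$order), toString(head(x$order, 3))))
  invisible(x)
}
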