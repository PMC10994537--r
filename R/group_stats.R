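#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return adjusted (monotone, <= 1) values in the input order
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify effect sizes the way parametric maps are reported
#'
#' moderate: |d| < 0.8; large: 0.8 <= |d| <= 1.2; very_large: |d| > 1.2.
#' @param d numeric vector of Cohen's d values
#' @return character vector
#' @export
d_class <- function(d) {
  ifelse(abs(d) < 0.8, "moderate",
         ifelse(abs(d) <= 1.2, "large", "very_large"))
}

#' Voxel-wise two-sample t maps with FDR-controlled z and effect-size maps
#'
#' Per in-mask voxel: unpaired two-tailed Student's t-test (pooled variance,
#' group A minus group B, so positive statistics mean higher mean in A),
#' Benjamini-Hochberg adjustment across the in-mask voxels, a signed z map
#' `z = sign(t) * qnorm(1 - p/2)` thresholded at adjusted p <= `alpha`
#' (zero elsewhere), and a Cohen's d map with pooled SD plus its
#' moderate/large/very-large classification. Voxels with zero pooled
#' variance get p = 1 (with a warning). Set `welch = TRUE` for the unpooled
#' variant.
#'
#' @param maps_a,maps_b lists of 3D arrays (one map per subject), >= 2 each
#' @param mask logical 3D array
#' @param alpha adjusted-p threshold for the z map (default 0.05)
#' @param welch use Welch's t instead of the pooled-variance Student's t
#' @return object of class `voxel_stat_maps` with 3D arrays `t`, `p`, `q`,
#'   `z`, `d`, a character array `d_class`, and the `mask`
#' @export
voxelwise_ttest <- function(maps_a, maps_b, mask, alpha = 0.05,
                            welch = FALSE) {
  na <- length(maps_a); nb <- length(maps_b)
  if (na < 2 || nb < 2) stop("need at least 2 subjects per group")
  vox <- which(as.vector(mask))
  A <- matrix(vapply(maps_a, function(m) as.vector(m)[vox],
                     numeric(length(vox))), nrow = length(vox))
  B <- matrix(vapply(maps_b, function(m) as.vector(m)[vox],
                     numeric(length(vox))), nrow = length(vox))
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, stats::var); vb <- apply(B, 1, stats::var)
  if (welch) {
    se2 <- va / na + vb / nb
    tt <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(tt))
  }
  zero_var <- !is.finite(tt)
  if (any(zero_var)) {
    warning(sprintf("%d voxels have zero pooled variance; p set to 1",
                    sum(zero_var)))
    tt[zero_var] <- 0
  }
  p <- 2 * stats::pt(-abs(tt), df)
  p[zero_var] <- 1
  q <- bh_fdr(p)
  z <- sign(tt) * stats::qnorm(1 - p / 2)
  z[q > alpha] <- 0
  sp <- if (welch) sqrt((va + vb) / 2) else
    sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  d <- (ma - mb) / sp
  d[!is.finite(d)] <- 0
  d3 <- dim(mask)
  as_map <- function(v, init = NA_real_) {
    m <- array(init, d3); m[vox] <- v; m
  }
  structure(list(t = as_map(tt), p = as_map(p), q = as_map(q),
                 z = as_map(z), d = as_map(d),
                 d_class = as_map(d_class(d), init = NA_character_),
                 mask = mask),
            class = "voxel_stat_maps")
}

#' Sample mean binding potentials over the analysis VOIs
#'
#' One row per subject x VOI with the subject's metadata attached. Rows
#' whose VOI intersects that subject's focal-lesion mask are flagged
#' `excluded = TRUE` (flagged, never silently dropped).
#'
#' @param bp_maps named list (by subject id) of 3D bp arrays or
#'   `parametric_map` objects
#' @param lmap a [label_map()]
#' @param voi_list character vector of VOI names (default:
#'   [default_voi_list()])
#' @param subjects data.frame of subject records with columns id, group,
#'   genotype, outcome, crs_r
#' @param lesion_masks optional named list (by subject id) of logical masks
#' @return data.frame of class `voi_table` with columns id, voi, bp, group,
#'   genotype, outcome, crs_r, excluded
#' @export
voi_table <- function(bp_maps, lmap, voi_list = default_voi_list(),
                      subjects, lesion_masks = NULL) {
  missing_voi <- setdiff(voi_list, unname(lmap$names))
  if (length(missing_voi))
    stop("VOIs missing from the label map: ",
         paste(missing_voi, collapse = ", "))
  rows <- list()
  for (sid in names(bp_maps)) {
    m <- bp_maps[[sid]]
    if (inherits(m, "parametric_map")) m <- m$bp
    rec <- subjects[subjects$id == sid, , drop = FALSE]
    if (nrow(rec) != 1) stop("subject record not found for ", sid)
    for (voi in voi_list) {
      vm <- region_mask(lmap, voi)
      lesioned <- !is.null(lesion_masks[[sid]]) &&
        any(vm & lesion_masks[[sid]])
      rows[[length(rows) + 1L]] <- data.frame(
        id = sid, voi = voi, bp = mean(m[vm], na.rm = TRUE),
        group = as.character(rec$group), genotype = rec$genotype,
        outcome = rec$outcome, crs_r = rec$crs_r,
        excluded = lesioned, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("voi_table", class(out))
  out
}

#' The 14 analysis VOIs (13 hypothesis regions + precentral control)
#' @export
default_voi_list <- function() {
  c("brainstem", "thalamus", "caudate", "globus_pallidum", "putamen",
    "corpus_callosum", "ACC", "PCC", "mPFC", "precuneus",
    "superior_parietal", "cuneus", "hippocampus", "precentral")
}

#' VOI table straight from a simulated cohort's measured binding
#'
#' Fast path used by the simulation studies: builds the same table as
#' [voi_table()] from the cohort generator's measured regional bp values,
#' without images.
#' @param cohort result of [simulate_cohort()]
#' @param voi_list VOI names
#' @export
cohort_voi_table <- function(cohort, voi_list = default_voi_list()) {
  rec <- cohort$records
  rows <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
    data.frame(id = rec$id[i], voi = voi_list,
               bp = cohort$measured_bp[i, voi_list],
               group = as.character(rec$group[i]), genotype = rec$genotype[i],
               outcome = rec$outcome[i], crs_r = rec$crs_r[i],
               excluded = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  class(rows) <- c("voi_table", class(rows))
  rows
}

#' Two-way ANOVA on the VOI table with a genotype covariate
#'
#' Fits `response ~ covariate + factor1 * factor2` and reports type-II F
#' statistics, degrees of freedom and p-values for both main effects, their
#' interaction and the covariate. Type-II sums of squares handle the
#' unbalanced group sizes. Rows flagged `excluded` are dropped first.
#'
#' @param tab a [voi_table()]-shaped data.frame
#' @param response response column (default `"bp"`)
#' @param factors two factor columns (default group and VOI)
#' @param covariate optional covariate column (default `"genotype"`; set
#'   NULL to omit, it is dropped automatically if it has < 2 levels)
#' @return data.frame with columns term, df, F, p
#' @export
two_way_anova <- function(tab, response = "bp",
                          factors = c("group", "voi"),
                          covariate = "genotype") {
  if (!is.null(tab$excluded)) tab <- tab[!tab$excluded, , drop = FALSE]
  for (f in factors)
    if (length(unique(tab[[f]])) < 2)
      stop(sprintf("factor '%s' has fewer than 2 levels", f))
  if (!is.null(covariate) && length(unique(tab[[covariate]])) < 2)
    covariate <- NULL
  y <- tab[[response]]
  if (stats::var(y) == 0) {
    terms <- c(covariate, factors, paste(factors, collapse = ":"))
    return(data.frame(term = terms, df = NA_real_, F = 0, p = 1))
  }
  rhs <- paste(c(covariate, paste(factors, collapse = " * ")), collapse = " + ")
  dat <- data.frame(.y = y, tab[, c(factors, covariate), drop = FALSE])
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
  a2 <- car::Anova(fit, type = 2)
  keep <- setdiff(rownames(a2), "Residuals")
  data.frame(term = keep, df = a2[keep, "Df"], F = a2[keep, "F value"],
             p = a2[keep, "Pr(>F)"], row.names = NULL)
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' Studentized-range adjusted pairwise comparisons of the levels of one
#' factor, optionally adjusting for other model terms.
#'
#' @param tab data.frame
#' @param factor factor column whose levels are compared
#' @param response response column
#' @param adjust_for optional character vector of additional additive model
#'   terms (e.g. a genotype covariate)
#' @return data.frame with columns comparison, diff, lwr, upr, p_adj
#' @export
tukey_hsd <- function(tab, factor = "group", response = "bp",
                      adjust_for = NULL) {
  lv <- unique(tab[[factor]])
  if (length(lv) < 2) stop("factor must have at least 2 levels")
  dat <- data.frame(.y = tab[[response]],
                    .f = base::factor(tab[[factor]]))
  rhs <- ".f"
  if (!is.null(adjust_for)) {
    for (a in adjust_for) dat[[a]] <- base::factor(tab[[a]])
    rhs <- paste(c(adjust_for, ".f"), collapse = " + ")
  }
  fit <- stats::aov(stats::as.formula(paste(".y ~", rhs)), data = dat)
  tk <- stats::TukeyHSD(fit, which = ".f")$.f
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL)
}

#' Within-VOI pairwise group comparisons from the group x VOI Tukey family
#'
#' Runs Tukey HSD over all group-by-VOI cell means (the post hoc family of
#' the two-way ANOVA) and returns only the comparisons of two groups within
#' the same VOI.
#'
#' @param tab a [voi_table()]-shaped data.frame
#' @param covariate optional covariate column name
#' @return data.frame with columns voi, comparison, diff, p_adj
#' @export
voi_pairwise_tukey <- function(tab, covariate = "genotype") {
  if (!is.null(tab$excluded)) tab <- tab[!tab$excluded, , drop = FALSE]
  dat <- data.frame(.y = tab$bp,
                    .cell = interaction(tab$group, tab$voi, sep = "|"))
  rhs <- ".cell"
  if (!is.null(covariate) && length(unique(tab[[covariate]])) > 1) {
    dat$.cov <- base::factor(tab[[covariate]])
    rhs <- ".cov + .cell"
  }
  fit <- stats::aov(stats::as.formula(paste(".y ~", rhs)), data = dat)
  tk <- stats::TukeyHSD(fit, which = ".cell")$.cell
  cmp <- rownames(tk)
  parts <- strsplit(cmp, "-", fixed = TRUE)
  lhs <- vapply(parts, `[`, character(1), 1)
  rhs2 <- vapply(parts, `[`, character(1), 2)
  voi_l <- sub("^[^|]*\\|", "", lhs)
  voi_r <- sub("^[^|]*\\|", "", rhs2)
  keep <- voi_l == voi_r
  data.frame(voi = voi_l[keep],
             comparison = paste(sub("\\|.*$", "", lhs[keep]),
                                sub("\\|.*$", "", rhs2[keep]), sep = "-"),
             diff = tk[keep, "diff"], p_adj = tk[keep, "p adj"],
             row.names = NULL)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Mid-rank tie handling. The two-sided p-value is computed by full
#' enumeration of the n! rank permutations for n <= 9 and by the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y numeric vectors, length >= 3, non-constant
#' @return list with `rho` and `p`
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need paired vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation is undefined for constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    P <- all_permutations(n)
    RY <- matrix(ry[P], nrow(P), n)
    s <- as.vector(RY %*% rx)
    mx <- mean(rx); my <- mean(ry)
    denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
    rho_perm <- (s - n * mx * my) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p)
}

# all permutations of 1..n as an n! x n matrix (n <= 9)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out[((i - 1) * nrow(sub) + 1):(i * nrow(sub)), ] <- block
  }
  out
}

#' Cohort descriptive tests with normality-based routing
#'
#' For each requested variable: categorical variables get a chi-square test
#' of independence with the grouping (no continuity correction); numeric
#' variables get a Shapiro-Wilk normality test per group, then a one-way
#' ANOVA when every group looks normal (all Shapiro p > 0.05) and a
#' Kruskal-Wallis test otherwise. The routing taken is recorded per
#' variable.
#'
#' @param tab data.frame, one row per subject
#' @param group_col grouping column name
#' @param vars variable names to test (default: all other columns)
#' @return data.frame with columns variable, test, statistic, df, p,
#'   shapiro_min_p
#' @export
descriptive_tests <- function(tab, group_col = "group",
                              vars = setdiff(names(tab), group_col)) {
  g <- base::factor(tab[[group_col]])
  if (any(table(g) == 0) || nlevels(g) < 2)
    stop("grouping must have >= 2 non-empty levels")
  rows <- lapply(vars, function(v) {
    x <- tab[[v]]
    if (is.numeric(x)) {
      sw <- vapply(split(x, g), function(xx) {
        if (length(unique(xx)) < 3) return(NA_real_)
        stats::shapiro.test(xx)$p.value
      }, numeric(1))
      normal <- all(is.na(sw) | sw > 0.05) && !all(is.na(sw))
      if (normal) {
        fit <- stats::aov(x ~ g)
        s <- summary(fit)[[1]]
        data.frame(variable = v, test = "anova", statistic = s$`F value`[1],
                   df = s$Df[1], p = s$`Pr(>F)`[1],
                   shapiro_min_p = min(sw, na.rm = TRUE))
      } else {
        kw <- stats::kruskal.test(x, g)
        data.frame(variable = v, test = "kruskal-wallis",
                   statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p = kw$p.value,
                   shapiro_min_p = suppressWarnings(min(sw, na.rm = TRUE)))
      }
    } else {
      ct <- stats::chisq.test(table(g, x), correct = FALSE)
      data.frame(variable = v, test = "chi-square",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 shapiro_min_p = NA_real_)
    }
  })
  do.call(rbind, rows)
}
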