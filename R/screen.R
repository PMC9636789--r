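# Population-scale screening: saturation catalogs of all possible PAS SNVs,
# allele-frequency enrichment of disruptive variants, elimination of
# variants protected by higher-impact common variants, and case/control
# gain-of-function testing.

#' Saturation screen of a PAS catalog
#'
#' Imputes the effect of every possible SNV (3 alternates per position) of
#' every PAS: predicted LOR and the induced change in isoform usage against
#' the per-PAS baseline.
#'
#' @param score_fn function(sequences) -> proximal isoform proportions; e.g.
#'   `function(s) proximalIsoform(pasForward(model, s))` for a trained
#'   network, or a ground-truth-law scorer for synthetic studies.
#' @param pas_df data.frame with columns `id` and `sequence`.
#' @param baselines per-PAS baseline isoform usage in (0, 1) (e.g. the mean
#'   wildtype usage across conditions), recycled if scalar.
#' @param chunk scoring batch size.
#' @return data.frame (one row per PAS x position x alternate): pas, offset
#'   (0-based), ref, alt, lor, delta_use.
#' @export
saturationScreen <- function(score_fn, pas_df, baselines = 0.5,
                             chunk = 512L) {
  stopifnot(all(baselines > 0), all(baselines < 1))
  baselines <- rep_len(baselines, nrow(pas_df))
  out <- vector("list", nrow(pas_df))
  for (p in seq_len(nrow(pas_df))) {
    s <- pas_df$sequence[p]
    L <- nchar(s)
    chars <- strsplit(s, "")[[1]]
    offs <- integer(0)
    alts <- character(0)
    vars <- character(0)
    for (i in seq_len(L)) {
      for (b in setdiff(DNA_BASES, chars[i])) {
        offs <- c(offs, i - 1L)
        alts <- c(alts, b)
        vars <- c(vars, substituteBase(s, i - 1L, b))
      }
    }
    y <- numeric(length(vars))
    for (st in seq(1L, length(vars), by = chunk)) {
      idx <- st:min(st + chunk - 1L, length(vars))
      y[idx] <- score_fn(vars[idx])
    }
    y_ref <- score_fn(s)
    lors <- lor(rep(y_ref, length(y)), y)
    out[[p]] <- data.frame(
      pas = pas_df$id[p], offset = offs, ref = chars[offs + 1L], alt = alts,
      lor = lors, delta_use = deltaUsage(lors, baselines[p])
    )
  }
  do.call(rbind, out)
}

#' Allele-frequency enrichment of disruptive variants
#'
#' For each allele-frequency class, the fraction of variants that are
#' disruptive (`delta_use` strictly below the threshold) relative to the
#' singleton class, with a two-sided rank-sum p-value comparing the
#' `delta_use` distributions against singletons.
#'
#' @param catalog data.frame with columns `af_class` (factor; must contain a
#'   "singleton" level) and `delta_use`.
#' @param threshold disruptive cutoff (default -0.15, strict inequality).
#' @return data.frame per class: n, frac_disruptive, enrichment (vs
#'   singletons; NA for empty classes), p_value.
#' @export
afEnrichment <- function(catalog, threshold = -0.15) {
  cls <- unique(as.character(catalog$af_class))
  if (!"singleton" %in% cls) stop("catalog must contain a singleton class")
  ref <- catalog$delta_use[catalog$af_class == "singleton"]
  ref_frac <- mean(ref < threshold)
  out <- lapply(cls, function(cl) {
    x <- catalog$delta_use[catalog$af_class == cl]
    frac <- if (length(x)) mean(x < threshold) else NA_real_
    p <- if (cl == "singleton" || length(x) == 0L) NA_real_ else
      suppressWarnings(wilcox.test(x, ref)$p.value)
    data.frame(af_class = cl, n = length(x), frac_disruptive = frac,
               enrichment = if (ref_frac > 0) frac / ref_frac else NA_real_,
               p_value = p)
  })
  do.call(rbind, out)
}

#' Remove cohort variants protected by higher-impact common variants
#'
#' A cohort variant is removed when its PAS carries common background
#' variants (allele frequency above `af_cutoff`) whose effect sizes dominate
#' it: strictly larger |LOR| when `fold_rule = NULL`, or at least
#' `fold_rule` times its |LOR| otherwise. With `binning = "five_bin"`,
#' background SNVs of a PAS are first binned by effect size into 5
#' equal-width bins and allele counts are aggregated per bin, so a group of
#' rare variants with comparable effects can take the role of one common
#' variant (the bin's largest |LOR| represents it). An optional neighbour
#' rule additionally removes variants in PASs with a downstream neighbouring
#' PAS within `neighbor_rule_nt`. When a variant id maps to several PASs it
#' is first assigned to the PAS with the largest predicted effect.
#'
#' @param cohort data.frame with columns `pas`, `lor` (and optionally `id`).
#' @param background data.frame with columns `pas`, `lor`, `allele_count`.
#' @param af_cutoff allele-frequency cutoff for "common" (default 1e-4, i.e.
#'   AF > 0.01\%).
#' @param fold_rule NULL for the strictly-larger rule or a numeric fold
#'   (e.g. 1.5).
#' @param binning "none" or "five_bin".
#' @param neighbor_rule_nt NULL, or the downstream-neighbour distance cutoff
#'   (requires `pas_info`).
#' @param pas_info data.frame with `id` and `downstream_neighbor_nt`.
#' @param allele_number total allele number used to convert counts to
#'   frequencies (default 150000).
#' @return list(cohort = retained rows, audit = data.frame logging each
#'   removal with the rule and the triggering background effect size).
#' @export
eliminateProtected <- function(cohort, background, af_cutoff = 1e-4,
                               fold_rule = NULL,
                               binning = c("none", "five_bin"),
                               neighbor_rule_nt = NULL, pas_info = NULL,
                               allele_number = 150000) {
  binning <- match.arg(binning)
  audit <- list()
  if (!is.null(cohort$id) && anyDuplicated(cohort$id)) {
    keep <- unlist(lapply(split(seq_len(nrow(cohort)), cohort$id),
                          function(ix) ix[which.max(abs(cohort$lor[ix]))]))
    dropped <- setdiff(seq_len(nrow(cohort)), keep)
    for (i in dropped) {
      audit[[length(audit) + 1L]] <- data.frame(
        row = i, pas = cohort$pas[i], rule = "multi_pas_assignment",
        trigger = NA_real_)
    }
    cohort <- cohort[sort(keep), , drop = FALSE]
  }
  # per-PAS dominating common effect size
  dominant <- function(p) {
    bg <- background[background$pas == p, , drop = FALSE]
    if (nrow(bg) == 0L) return(NA_real_)
    if (binning == "five_bin") {
      rng <- range(bg$lor)
      edges <- if (diff(rng) == 0) c(rng[1L] - 1e-9, rng[2L] + 1e-9) else
        seq(rng[1L] - 1e-9, rng[2L] + 1e-9, length.out = 6L)
      bin <- cut(bg$lor, edges, include.lowest = TRUE)
      ac <- tapply(bg$allele_count, bin, sum)
      eff <- tapply(abs(bg$lor), bin, max)
      common <- !is.na(ac) & (ac / allele_number > af_cutoff)
      if (!any(common)) return(NA_real_)
      max(eff[common])
    } else {
      common <- bg$allele_count / allele_number > af_cutoff
      if (!any(common)) return(NA_real_)
      max(abs(bg$lor[common]))
    }
  }
  dom <- vapply(unique(cohort$pas), dominant, numeric(1))
  names(dom) <- as.character(unique(cohort$pas))
  removed <- logical(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    d <- dom[as.character(cohort$pas[i])]
    if (is.na(d)) next
    hit <- if (is.null(fold_rule)) d > abs(cohort$lor[i])
           else d >= fold_rule * abs(cohort$lor[i])
    if (hit) {
      removed[i] <- TRUE
      audit[[length(audit) + 1L]] <- data.frame(
        row = i, pas = cohort$pas[i], rule = if (is.null(fold_rule))
          "common_strictly_larger" else sprintf("common_%gx", fold_rule),
        trigger = unname(d))
    }
  }
  if (!is.null(neighbor_rule_nt)) {
    if (is.null(pas_info)) stop("neighbor rule requires pas_info")
    near <- pas_info$id[pas_info$downstream_neighbor_nt < neighbor_rule_nt]
    for (i in which(!removed & cohort$pas %in% near)) {
      removed[i] <- TRUE
      audit[[length(audit) + 1L]] <- data.frame(
        row = i, pas = cohort$pas[i], rule = "downstream_neighbor",
        trigger = pas_info$downstream_neighbor_nt[
          match(cohort$pas[i], pas_info$id)])
    }
  }
  list(cohort = cohort[!removed, , drop = FALSE],
       audit = if (length(audit)) do.call(rbind, audit) else
         data.frame(row = integer(0), pas = integer(0),
                    rule = character(0), trigger = numeric(0)))
}

#' Case/control comparison of predicted variant effects
#'
#' Rank-sum tests (two-sided and one-sided case > control) on the LOR
#' distributions, plus the gain-of-function fold enrichment and Fisher exact
#' test from the 2x2 table of (cohort x above/below threshold). A zero cell
#' yields a Haldane-corrected odds ratio alongside the exact test.
#'
#' @param case_lors,ctrl_lors predicted LORs for the two groups (nonempty).
#' @param gof_threshold gain-of-function cutoff on the LOR (default ln 2).
#' @return list(wilcox_p, wilcox_p_greater, fold, fisher_p, odds_ratio,
#'   table).
#' @export
cohortCompare <- function(case_lors, ctrl_lors, gof_threshold = log(2)) {
  stopifnot(length(case_lors) > 0, length(ctrl_lors) > 0)
  gof_case <- sum(case_lors > gof_threshold)
  gof_ctrl <- sum(ctrl_lors > gof_threshold)
  tab <- matrix(c(gof_case, length(case_lors) - gof_case,
                  gof_ctrl, length(ctrl_lors) - gof_ctrl),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("case", "control"),
                                c("gof", "not_gof")))
  rate_case <- gof_case / length(case_lors)
  rate_ctrl <- gof_ctrl / length(ctrl_lors)
  fold <- if (gof_case == 0L && gof_ctrl == 0L) NA_real_
          else if (rate_ctrl == 0) Inf else rate_case / rate_ctrl
  ft <- fisher.test(tab)
  orh <- ((gof_case + 0.5) * (length(ctrl_lors) - gof_ctrl + 0.5)) /
    ((length(case_lors) - gof_case + 0.5) * (gof_ctrl + 0.5))
  list(
    wilcox_p = suppressWarnings(wilcox.test(case_lors, ctrl_lors)$p.value),
    wilcox_p_greater = suppressWarnings(
      wilcox.test(case_lors, ctrl_lors, alternative = "greater")$p.value),
    fold = fold, fisher_p = ft$p.value,
    odds_ratio = if (any(tab == 0)) orh else unname(ft$estimate),
    table = tab
  )
}
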