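#' Assign weight-gain prone and resistant cohorts
#'
#' Ranks animals by total weight gain (last recorded day minus day 0) and
#' labels the `k` largest gainers "prone" and the `k` smallest
#' "resistant". Ties at either boundary are broken deterministically by
#' ascending animal id, so row order never changes the result.
#'
#' @param cohort A cohort table: tibble with columns `animal_id, day,
#'   body_weight` (one weight per animal and day; day 0 and the last day
#'   must be present for every animal).
#' @param k Cohort size (default 5: top five / bottom five).
#' @return A tibble of class `cohort_assignment` with one row per animal:
#'   `animal_id, delta_weight, cohort` (`"prone"`, `"resistant"` or
#'   `"intermediate"`), sorted by descending gain. Convenience accessors:
#'   [prone_ids()], [resistant_ids()].
#' @export
assign_cohorts <- function(cohort, k = 5) {
  need <- c("animal_id", "day", "body_weight")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    abort(paste0("cohort table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(cohort$body_weight <= 0, na.rm = TRUE)) abort("body weights must be > 0")
  last_day <- max(cohort$day)
  ends <- cohort |>
    dplyr::filter(.data$day %in% c(0, last_day)) |>
    dplyr::distinct(.data$animal_id, .data$day, .keep_all = TRUE)
  n_animals <- dplyr::n_distinct(cohort$animal_id)
  if (n_animals < 2 * k) {
    abort(sprintf("need at least %d animals for k = %d, got %d", 2 * k, k, n_animals))
  }
  counts <- ends |> dplyr::count(.data$animal_id)
  incomplete <- counts$animal_id[counts$n < 2L]
  if (length(incomplete)) {
    abort(sprintf("animal(s) missing day 0 or day %d weight: %s", last_day,
                  paste(incomplete, collapse = ", ")))
  }
  dw <- ends |>
    tidyr::pivot_wider(id_cols = "animal_id", names_from = "day",
                       values_from = "body_weight", names_prefix = "d") |>
    dplyr::mutate(delta_weight = .data[[paste0("d", last_day)]] - .data$d0) |>
    dplyr::select("animal_id", "delta_weight") |>
    dplyr::arrange(dplyr::desc(.data$delta_weight), .data$animal_id)
  n <- nrow(dw)
  cohort_lab <- rep("intermediate", n)
  cohort_lab[seq_len(k)] <- "prone"
  # resistant = k smallest gains among animals not already prone, tie-broken
  # by ascending animal id; picking prone first keeps the sets disjoint even
  # when one tie block spans both boundaries.
  rest <- which(cohort_lab != "prone")
  res_idx <- rest[order(dw$delta_weight[rest], dw$animal_id[rest])][seq_len(k)]
  cohort_lab[res_idx] <- "resistant"
  out <- dplyr::mutate(dw, cohort = cohort_lab)
  structure(out, class = c("cohort_assignment", class(out)), k = k,
            last_day = last_day)
}

#' @param x A `cohort_assignment`.
#' @rdname assign_cohorts
#' @export
prone_ids <- function(x) sort(x$animal_id[x$cohort == "prone"])

#' @rdname assign_cohorts
#' @export
resistant_ids <- function(x) sort(x$animal_id[x$cohort == "resistant"])

#' Per-group summary with percent difference of means
#'
#' Computes mean, standard error of the mean and n per group, plus the
#' percent difference of the comparison group's mean relative to the
#' reference group: `100 * (mean_comp - mean_ref) / mean_ref`, reported
#' unrounded and to the nearest integer.
#'
#' @param data A tibble with one value per animal (or sample).
#' @param value,group Column names (strings) of the value and group label.
#' @param reference Reference group label (the denominator); default the
#'   second group in sort order.
#' @param comparison Comparison group label; default the other group.
#' @return A list of class `group_summary`: `groups` (tibble `group, n,
#'   mean, sem`), `abs_diff`, `pct_diff`, `pct_diff_rounded`, `reference`,
#'   `comparison`. `tidy()` returns the per-group tibble.
#' @examples
#' d <- tibble::tibble(g = rep(c("prone", "resistant"), each = 5),
#'                     v = rep(c(3.1, 2.6), each = 5))
#' group_summary(d, "v", "g", reference = "resistant")$pct_diff_rounded # 19
#' @export
group_summary <- function(data, value, group, reference = NULL,
                          comparison = NULL) {
  g <- data |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data[[value]]),
                     sem = stats::sd(.data[[value]]) / sqrt(dplyr::n()),
                     .groups = "drop")
  if (any(g$n == 0L) || nrow(g) < 2L) abort("need two non-empty groups")
  labs <- sort(unique(g$group))
  reference <- reference %||% labs[[2L]]
  comparison <- comparison %||% setdiff(labs, reference)[[1L]]
  if (!all(c(reference, comparison) %in% g$group)) {
    abort("reference/comparison labels not present in the data")
  }
  m_ref <- g$mean[g$group == reference]
  m_cmp <- g$mean[g$group == comparison]
  pct <- 100 * (m_cmp - m_ref) / m_ref
  structure(list(groups = g, abs_diff = m_cmp - m_ref, pct_diff = pct,
                 pct_diff_rounded = round(pct), reference = reference,
                 comparison = comparison),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  print(x$groups)
  cat(sprintf("%s vs %s: %+.3g absolute, %+.4g%% (~%+d%%)\n", x$comparison,
              x$reference, x$abs_diff, x$pct_diff, x$pct_diff_rounded))
  invisible(x)
}

#' @export
tidy.group_summary <- function(x, ...) x$groups

#' @export
glance.group_summary <- function(x, ...) {
  tibble(reference = x$reference, comparison = x$comparison,
         abs_diff = x$abs_diff, pct_diff = x$pct_diff,
         pct_diff_rounded = x$pct_diff_rounded)
}

#' Delta-delta-Ct relative expression
#'
#' Standard relative qPCR quantification: per sample,
#' `dCt = Ct_target - mean(Ct_housekeeping)` (arithmetic mean of the
#' housekeeping Ct values, i.e. geometric mean of their expression);
#' per gene, `ddCt = dCt - mean(dCt of the reference group)`; relative
#' quantity `RQ = 2^-ddCt`. By construction the reference group's
#' geometric-mean RQ is 1 for every gene.
#'
#' @param records Long-format qPCR tibble: `sample_id, group, gene, ct`.
#' @param housekeeping Character vector of housekeeping gene names
#'   (default `c("Pgk1", "Hprt")`); every sample must carry a finite Ct
#'   for each.
#' @param reference_group Group label used as the ddCt baseline.
#' @return A list of class `ddct_result`: `samples` (tibble `sample_id,
#'   group, gene, dct, ddct, rq`) and `groups` (tibble `gene, group, n,
#'   mean_rq, sem_rq`). `tidy()` returns the sample-level tibble.
#' @export
ddct_relative_expression <- function(records, housekeeping = c("Pgk1", "Hprt"),
                                     reference_group = "resistant") {
  need <- c("sample_id", "group", "gene", "ct")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort(paste0("qPCR table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyNA(records$ct) || any(!is.finite(records$ct))) {
    abort("qPCR table: non-finite Ct values")
  }
  hk_key <- key_of(housekeeping)
  is_hk <- key_of(records$gene) %in% hk_key
  hk <- records[is_hk, ] |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(hk_mean = mean(.data$ct), hk_n = dplyr::n(),
                     .groups = "drop")
  short <- setdiff(unique(records$sample_id),
                   hk$sample_id[hk$hk_n == length(housekeeping)])
  if (length(short)) {
    abort(sprintf("sample(s) missing housekeeping Ct values: %s",
                  paste(short, collapse = ", ")))
  }
  targets <- records[!is_hk, ]
  if (nrow(targets) == 0L) abort("no target-gene rows in the qPCR table")
  if (!reference_group %in% targets$group) {
    abort(sprintf("reference group '%s' not present", reference_group))
  }
  d <- targets |>
    dplyr::left_join(hk, by = "sample_id") |>
    dplyr::mutate(dct = .data$ct - .data$hk_mean) |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(ddct = .data$dct -
                    mean(.data$dct[.data$group == reference_group])) |>
    dplyr::ungroup() |>
    dplyr::mutate(rq = 2^(-.data$ddct)) |>
    dplyr::select("sample_id", "group", "gene", "dct", "ddct", "rq")
  g <- d |>
    dplyr::group_by(.data$gene, .data$group) |>
    dplyr::summarise(n = dplyr::n(), mean_rq = mean(.data$rq),
                     sem_rq = stats::sd(.data$rq) / sqrt(dplyr::n()),
                     .groups = "drop")
  structure(list(samples = d, groups = g, reference_group = reference_group,
                 housekeeping = housekeeping),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("<ddct_result> %d genes, reference group '%s'\n",
              dplyr::n_distinct(x$samples$gene), x$reference_group))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.ddct_result <- function(x, ...) x$samples

#' Per-gene Welch t screen with two-stage adaptive FDR
#'
#' For each gene, compares the two groups with Welch's unequal-variance t
#' test (Welch-Satterthwaite degrees of freedom, two-sided p), then flags
#' rejections with the two-stage step-up procedure of Benjamini, Krieger
#' and Yekutieli at the given FDR level (default 0.10): stage one applies
#' Benjamini-Hochberg at level `fdr / (1 + fdr)` to estimate the number
#' of true nulls, stage two re-applies the step-up at the adaptively
#' inflated level. Genes where both groups have zero variance get `t = 0,
#' p = 1` when the means are equal and an error otherwise.
#'
#' @param data Long tibble with one row per observation.
#' @param value,group,gene Column names (strings).
#' @param fdr FDR level for the two-stage procedure, default 0.10.
#' @param shapiro Optionally run a per-gene Shapiro-Wilk normality check
#'   (on the pooled residuals) and report its p-value; the screen itself
#'   never branches on it.
#' @return A tibble, one row per gene: `gene, n1, n2, estimate, t, df, p,
#'   reject` (plus `shapiro_p` if requested), sorted by p.
#' @export
welch_bky_screen <- function(data, value = "value", group = "group",
                             gene = "gene", fdr = 0.10, shapiro = FALSE) {
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1) abort("fdr must lie in (0, 1)")
  labs <- sort(unique(data[[group]]))
  if (length(labs) != 2L) abort("exactly two groups are required")
  per_gene <- split(data, data[[gene]])
  rows <- purrr::imap(per_gene, function(d, g) {
    x <- d[[value]][d[[group]] == labs[[1L]]]
    y <- d[[value]][d[[group]] == labs[[2L]]]
    if (length(x) < 2L || length(y) < 2L) {
      abort(sprintf("gene %s: need >= 2 values per group", g))
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        res <- tibble(gene = g, n1 = length(x), n2 = length(y),
                      estimate = 0, t = 0, df = NA_real_, p = 1)
      } else {
        abort(sprintf("gene %s: zero variance in both groups with unequal means", g))
      }
    } else {
      tt <- t.test(x, y, var.equal = FALSE)
      res <- tibble(gene = g, n1 = length(x), n2 = length(y),
                    estimate = unname(diff(rev(tt$estimate))),
                    t = unname(tt$statistic), df = unname(tt$parameter),
                    p = tt$p.value)
    }
    if (shapiro) {
      resid <- c(x - mean(x), y - mean(y))
      res$shapiro_p <- tryCatch(stats::shapiro.test(resid)$p.value,
                                error = function(e) NA_real_)
    }
    res
  })
  out <- dplyr::bind_rows(rows)
  out$reject <- bky_reject(out$p, fdr = fdr)
  dplyr::arrange(out, .data$p, .data$gene)
}

#' Two-stage Benjamini-Krieger-Yekutieli rejections
#'
#' The adaptive two-stage linear step-up procedure: apply
#' Benjamini-Hochberg at level `q' = fdr / (1 + fdr)`; if it rejects `r1`
#' of `m` hypotheses with `0 < r1 < m`, estimate `m0 = m - r1` true nulls
#' and re-apply the step-up at level `q' * m / m0`, rejecting at stage
#' two. If `r1 = 0` nothing is rejected; if `r1 = m` everything is.
#'
#' @param p Numeric vector of p-values.
#' @param fdr Target FDR level.
#' @return Logical vector of rejections, aligned with `p`.
#' @export
bky_reject <- function(p, fdr = 0.10) {
  if (length(p) == 0L) return(logical())
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  m <- length(p)
  q1 <- fdr / (1 + fdr)
  stage1 <- bh_reject(p, q1)
  r1 <- sum(stage1)
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh_reject(p, q1 * m / (m - r1))
}

# Linear step-up (Benjamini-Hochberg) rejection at level alpha.
bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- p[o] <= alpha * seq_len(m) / m
  k <- if (any(ok)) max(which(ok)) else 0L
  reject <- rep(FALSE, m)
  if (k > 0L) reject[o[seq_len(k)]] <- TRUE
  reject
}

#' Read a long-format qPCR CSV (`sample_id, group, gene, ct`)
#'
#' @param path Path to the CSV.
#' @return A tibble.
#' @export
read_qpcr_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  miss <- setdiff(c("sample_id", "group", "gene", "ct"), names(x))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  }
  as_tibble(x)
}
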