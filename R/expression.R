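# Binding-versus-expression trend and the knockdown volcano.

#' Relate TSS-proximal tag counts to gene expression
#'
#' For every gene, counts tags whose 5' end lies within `tss_half_window` of
#' the TSS and pairs that with the gene's expression level; a loess trend is
#' fitted over a 100-point grid and a Spearman correlation returned. On data
#' where CxxC binding tracks nonmethylated CpG rather than transcription,
#' the trend is flat and |rho| small.
#'
#' @param tags A [tag_collection()].
#' @param genes Tibble with `chrom`, `start`, `end`, `strand`, `gene`.
#' @param expression Either a per-gene tibble (`gene`, `expr`) or a long
#'   control/knockdown table from [simulate_expression()] (control means are
#'   used, log2 scale).
#' @param tss_half_window Half-window around the TSS in bp.
#' @param loess_span Span of the loess smoother.
#' @return A `binding_expression` list: `data` (gene, expr, tags), `trend`
#'   (100-point grid tibble `expr`, `fit`), `rho` (Spearman; 0 when the tag
#'   counts are constant, NA with `flag = "constant expression"` when
#'   expression is).
#' @export
expression_vs_tags <- function(tags, genes, expression,
                               tss_half_window = 1000, loess_span = 0.3) {
  genes <- as_tibble(genes)
  expression <- as_tibble(expression)
  if ("condition" %in% names(expression)) {
    expression <- expression %>%
      filter(.data$condition == "control") %>%
      group_by(.data$gene) %>%
      summarise(expr = log2(mean(.data$expr)), .groups = "drop")
  }
  stopifnot(all(c("gene", "expr") %in% names(expression)))
  df <- left_join(genes, expression, by = "gene")
  df <- filter(df, !is.na(.data$expr))
  if (nrow(df) < 10) abort("need expression for >= 10 genes.")
  tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$tags <- vapply(seq_len(nrow(df)), function(i) {
    sum(tags$chrom == df$chrom[i] &
          tags$pos >= tss[i] - tss_half_window &
          tags$pos < tss[i] + tss_half_window)
  }, double(1))
  flag <- NULL
  if (sd(df$expr) == 0) {
    rho <- NA_real_
    flag <- "constant expression"
    trend <- tibble(expr = rep(df$expr[1], 100), fit = mean(df$tags))
  } else if (sd(df$tags) == 0) {
    # constant counts: flat trend, no association
    rho <- 0
    grid <- seq(min(df$expr), max(df$expr), length.out = 100)
    trend <- tibble(expr = grid, fit = df$tags[1])
  } else {
    rho <- suppressWarnings(cor(df$expr, df$tags, method = "spearman"))
    lo <- loess(tags ~ expr, data = df, span = loess_span,
                degree = 1, family = "symmetric")
    grid <- seq(min(df$expr), max(df$expr), length.out = 100)
    trend <- tibble(expr = grid, fit = predict(lo, newdata = tibble(expr = grid)))
  }
  structure(list(
    data = select(df, "gene", "expr", "tags"), trend = trend,
    rho = rho, flag = flag
  ), class = "binding_expression")
}

#' @export
print.binding_expression <- function(x, ...) {
  cat(sprintf("<binding_expression> %d genes; Spearman rho = %s%s\n",
              nrow(x$data), format(x$rho, digits = 3),
              if (is.null(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' Knockdown-versus-control volcano analysis
#'
#' Per transcript: log2 fold change of mean knockdown over mean control
#' expression, and a two-sided two-sample t-test (pooled variance) on
#' log2 expression values. Transcripts with a nonpositive mean in either
#' condition are excluded and reported in the `excluded` attribute.
#'
#' @param expr Long expression tibble: `gene`, `condition`
#'   ("control"/"knockdown"), `expr` (linear scale); >= 2 replicates per
#'   condition.
#' @return A tibble ordered by p: `gene`, `log2fc`, `statistic`, `p_value`.
#' @export
volcano <- function(expr) {
  expr <- as_tibble(expr)
  stopifnot(all(c("gene", "condition", "expr") %in% names(expr)))
  counts <- expr %>% dplyr::count(.data$gene, .data$condition)
  if (any(counts$n < 2)) abort("need >= 2 replicates per condition.")
  res <- expr %>%
    group_by(.data$gene) %>%
    summarise(
      m_ctl = mean(.data$expr[.data$condition == "control"]),
      m_kd = mean(.data$expr[.data$condition == "knockdown"]),
      tt = list(pooled_t(log2(pmax(.data$expr[.data$condition == "knockdown"], 1e-300)),
                         log2(pmax(.data$expr[.data$condition == "control"], 1e-300)))),
      .groups = "drop"
    )
  excluded <- res$gene[res$m_ctl <= 0 | res$m_kd <= 0]
  res <- filter(res, .data$m_ctl > 0, .data$m_kd > 0)
  out <- res %>%
    mutate(
      log2fc = log2(.data$m_kd / .data$m_ctl),
      statistic = purrr::map_dbl(.data$tt, 1),
      p_value = purrr::map_dbl(.data$tt, 2)
    ) %>%
    select("gene", "log2fc", "statistic", "p_value") %>%
    arrange(.data$p_value)
  attr(out, "excluded") <- excluded
  out
}

# Two-sided pooled-variance two-sample t-test; degenerate zero-variance
# zero-difference case returns (0, 1).
#' @noRd
pooled_t <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  d <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (d == 0) return(c(0, 1))
    return(c(sign(d) * Inf, 0))
  }
  tstat <- d / sqrt(sp2 * (1 / nx + 1 / ny))
  c(tstat, 2 * stats::pt(-abs(tstat), nx + ny - 2))
}
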