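# Percent-of-input enrichment over amplicons, H3 normalization, and the
# paired promoter-versus-body depletion test.

#' Library-size-normalised percent-of-input enrichment
#'
#' For each amplicon, computes (IP fragment-bp density / IP total tags)
#' divided by (input fragment-bp density / input total tags), times 100 — a
#' sequencing stand-in for ChIP-qPCR percent input. An amplicon with zero
#' input density is flagged `undefined` and should be excluded downstream.
#'
#' @param ip,input [tag_collection()]s.
#' @param amplicons Tibble with `chrom`, `start`, `end` and any annotation
#'   columns (typically `gene` and `region` in {"promoter","body"}).
#' @param fragment_length Override for both collections' fragment length.
#' @return An enrichment table: the amplicon columns plus `track`,
#'   `percent_input`, `undefined`.
#' @export
percent_input <- function(ip, input, amplicons, fragment_length = NULL) {
  amplicons <- as_tibble(amplicons)
  fl_ip <- frag_len(ip, fragment_length)
  fl_in <- frag_len(input, fragment_length)
  n_ip <- max(nrow(ip), 1L)
  n_in <- nrow(input)
  if (n_in == 0L) abort("input track is empty.")
  dens <- function(tags, fl, row) {
    cov <- fragment_coverage(tags, row$chrom, fl, row$end)
    sum(as.numeric(S4Vectors::window(cov, row$start + 1L, row$end))) /
      (row$end - row$start)
  }
  vals <- purrr::map_dfr(seq_len(nrow(amplicons)), function(i) {
    row <- amplicons[i, ]
    d_ip <- dens(ip, fl_ip, row)
    d_in <- dens(input, fl_in, row)
    if (d_in == 0) {
      tibble(percent_input = NA_real_, undefined = TRUE)
    } else {
      tibble(percent_input = 100 * (d_ip / n_ip) / (d_in / n_in),
             undefined = FALSE)
    }
  })
  bind_cols(amplicons, tibble(track = attr(ip, "track") %||% "IP"), vals)
}

#' Normalise a modification enrichment table to histone H3 occupancy
#'
#' Divides each amplicon's percent-input value for the modification by the
#' matched H3 value, removing nucleosome-density effects. Amplicons with H3
#' value 0 (or undefined on either side) come back `undefined`.
#'
#' @param mod_table,h3_table Enrichment tables from [percent_input()] over
#'   the same amplicon set.
#' @return `mod_table` with an added `h3_normalized` column.
#' @export
h3_normalize <- function(mod_table, h3_table) {
  keys <- intersect(c("chrom", "start", "end", "gene", "region"),
                    intersect(names(mod_table), names(h3_table)))
  h3 <- h3_table %>%
    select(dplyr::all_of(keys), h3_percent = "percent_input",
           h3_undefined = "undefined")
  out <- left_join(as_tibble(mod_table), h3, by = keys)
  if (any(is.na(out$h3_percent) & !out$h3_undefined %in% TRUE)) {
    abort("amplicon sets of `mod_table` and `h3_table` do not match.")
  }
  out %>%
    mutate(
      undefined = .data$undefined | .data$h3_undefined %in% TRUE |
        .data$h3_percent %in% 0,
      h3_normalized = if_else(.data$undefined, NA_real_,
                              .data$percent_input / .data$h3_percent)
    ) %>%
    select(-"h3_percent", -"h3_undefined")
}

#' Paired promoter-versus-body test
#'
#' Two-sided test of whether a (typically H3-normalised) enrichment differs
#' between each gene's promoter and body amplicons. The default is a paired
#' t-test on per-gene (promoter - body) values; `method = "welch"` gives an
#' unpaired Welch alternative.
#'
#' @param table Enrichment table with `gene`, `region`
#'   ("promoter"/"body") and the value column.
#' @param value Name of the value column (default `"h3_normalized"`).
#' @param method `"paired"` (default) or `"welch"`.
#' @return One-row tibble: `statistic`, `p_value`, `n` (genes with both
#'   values), `method`. With identical promoter and body values throughout,
#'   the statistic is 0 and p is 1.
#' @export
promoter_body_test <- function(table, value = "h3_normalized",
                               method = c("paired", "welch")) {
  method <- match.arg(method)
  tb <- as_tibble(table)
  stopifnot(all(c("gene", "region") %in% names(tb)), value %in% names(tb))
  if ("undefined" %in% names(tb)) tb <- filter(tb, !.data$undefined)
  wide <- tb %>%
    select("gene", "region", val = dplyr::all_of(value)) %>%
    tidyr::pivot_wider(names_from = "region", values_from = "val",
                       values_fn = mean) %>%
    filter(!is.na(.data$promoter), !is.na(.data$body))
  n <- nrow(wide)
  if (n < 3) abort("need >= 3 genes with both promoter and body values.")
  if (method == "paired") {
    d <- wide$promoter - wide$body
    if (all(d == 0)) {
      return(tibble(statistic = 0, p_value = 1, n = n, method = "paired t"))
    }
    tt <- t.test(d)
    tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
           n = n, method = "paired t")
  } else {
    tt <- t.test(wide$promoter, wide$body)
    tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
           n = n, method = "Welch t")
  }
}
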