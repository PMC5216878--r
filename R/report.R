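# Report assembly: transcription fixtures of the published summary tables
# and the arithmetic checks that reproduce the printed headline numbers
# from them.

.FIXTURE_MD5 <- c(
  printed_diversity_summary.tsv = "6ac2948eb0f1d4f2f9e0e35af6082915",
  printed_loss_of_diversity.tsv = "b34309cd4fb92aa7f76eed88859fc385",
  printed_fst_mutation_table.tsv = "5e12893f59af60245847fe3f91380dfe",
  printed_mutation_category_counts.tsv = "3bd847cb3d5e4c4a817be5a49c729896",
  printed_summaries.tsv = "4007c600552c10abd35954a36a427fb3")

#' Load the transcribed summary-table fixtures
#'
#' Machine-readable transcriptions of the reference study's printed
#' summaries: the per-region diversity summary (means/sums over 49 loci),
#' the loss-of-diversity table, the per-locus FST and shared/private
#' mutation table (with its `na` and `/` sentinel cells typed as NA
#' strings), the coding mutation-category counts, and the printed headline
#' values used for comparison. File checksums are verified unless
#' `verify = FALSE`.
#'
#' @param dir fixture directory (default: the installed package's extdata).
#' @param verify check md5 checksums (default TRUE).
#' @return list with `diversity`, `loss`, `fst`, `categories`, `printed`.
#' @export
load_printed_tables <- function(dir = system.file("extdata",
                                                  package = "beanscan"),
                                verify = TRUE) {
  files <- names(.FIXTURE_MD5)
  paths <- file.path(dir, files)
  if (verify) {
    got <- tools::md5sum(paths)
    bad <- files[is.na(got) | got != .FIXTURE_MD5]
    if (length(bad))
      stop("fixture checksum mismatch: ", paste(bad, collapse = ", "))
  }
  rd <- function(f) read.table(file.path(dir, f), sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE, check.names = FALSE)
  list(diversity = rd("printed_diversity_summary.tsv"),
       loss = rd("printed_loss_of_diversity.tsv"),
       fst = rd("printed_fst_mutation_table.tsv"),
       categories = rd("printed_mutation_category_counts.tsv"),
       printed = rd("printed_summaries.tsv"))
}

#' Recompute the printed headline summaries from the table fixtures
#'
#' From the transcribed per-region means and per-locus cells, recomputes:
#' mean-based loss-of-diversity statistics (`L = 1 - mean_MD/mean_MW` for
#' pi and theta, per region), the wild/domesticated fold-ratios of mean pi,
#' per-region mean FST over defined cells and the count of
#' significance-flagged loci, the shared/private mutation column totals,
#' and the percentage breakdown of coding mutation categories. Each value
#' is rounded to the printed precision and compared to the printed number.
#'
#' @param tables fixture list from [load_printed_tables()].
#' @return data.frame `quantity, computed, printed, match` with attribute
#'   `pass` (all printed values matched).
#' @export
replicate_printed_summaries <- function(tables = load_printed_tables()) {
  t1 <- tables$diversity; t4 <- tables$fst; f2 <- tables$categories
  printed <- tables$printed
  val <- function(stat, region, pop) {
    t1[[pop]][t1$statistic == stat & t1$region == region]
  }
  computed <- list()
  for (rg in c("whole", "coding", "noncoding")) {
    lpi <- loss_of_diversity(val("pi_x1000", rg, "MW"),
                             val("pi_x1000", rg, "MD"))$L
    lth <- loss_of_diversity(val("theta_x1000", rg, "MW"),
                             val("theta_x1000", rg, "MD"))$L
    computed[[paste0("L_pi_", rg)]] <- lpi
    computed[[paste0("L_theta_", rg)]] <- lth
    computed[[paste0("fold_pi_", rg)]] <-
      val("pi_x1000", rg, "MW") / val("pi_x1000", rg, "MD")
    f <- suppressWarnings(as.numeric(t4[[paste0("fst_", rg)]]))
    sig <- suppressWarnings(as.numeric(t4[[paste0("sig_", rg)]]))
    computed[[paste0("mean_fst_", rg)]] <- mean(f, na.rm = TRUE)
    if (rg == "whole")
      computed[["n_significant_whole"]] <- sum(sig > 0, na.rm = TRUE)
    for (cc in c("SM", "PMW", "PMD"))
      computed[[paste0(cc, "_total_", rg)]] <-
        sum(suppressWarnings(as.numeric(t4[[paste0(cc, "_", rg)]])),
            na.rm = TRUE)
  }
  for (tp in c("synonymous", "replacement")) {
    cnt <- f2$count[f2$type == tp]
    names(cnt) <- f2$category[f2$type == tp]
    pre <- if (tp == "synonymous") "pct_syn_" else "pct_rep_"
    for (cat in names(cnt))
      computed[[paste0(pre, sub("private_", "private_", cat))]] <-
        100 * cnt[[cat]] / sum(cnt)
  }
  rows <- lapply(printed$quantity, function(q) {
    cv <- computed[[q]]
    if (is.null(cv)) return(NULL)
    dg <- printed$digits[printed$quantity == q]
    pv <- printed$printed[printed$quantity == q]
    data.frame(quantity = q, computed = round(cv, dg), printed = pv,
               match = isTRUE(all.equal(round(cv, dg), pv)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pass") <- all(out$match)
  out
}
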