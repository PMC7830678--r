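# Candidate active-ingredient selection: ADME thresholds (oral
# bioavailability and drug-likeness) plus a literature-mined whitelist that
# keeps pharmacologically established compounds failing the thresholds.

validate_compound_table <- function(table) {
  need <- c("herb", "compound", "ob", "dl", "whitelisted")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0L)
    stop("compound table lacks column(s): ", paste(missing, collapse = ", "))
  bad <- which(is.na(table$ob) | table$ob < 0)
  if (length(bad) > 0L)
    stop("invalid OB (must be >= 0) in row ", bad[1L], " (",
         table$compound[bad[1L]], ")")
  bad <- which(is.na(table$dl) | table$dl < 0 | table$dl > 1)
  if (length(bad) > 0L)
    stop("invalid DL (must be in [0, 1]) in row ", bad[1L], " (",
         table$compound[bad[1L]], ")")
  if (anyDuplicated(table[c("herb", "compound")]))
    stop("duplicate (herb, compound) pair in compound table")
  invisible(table)
}

#' Screen compounds by ADME thresholds plus whitelist
#'
#' Retains every record with OB >= `ob_min` AND DL >= `dl_min` (both
#' inclusive), plus every whitelisted record regardless of its scores. Input
#' order is preserved. Each retained record is tagged with its provenance:
#' `"threshold"` if it passes both cut-offs (even when also whitelisted),
#' `"whitelist"` if kept only by the flag.
#'
#' @param table data.frame of compound records with columns herb, compound,
#'   ob (percent, >= 0), dl (in `[0, 1]`), whitelisted (logical).
#' @param ob_min oral-bioavailability threshold, percent; default 30.
#' @param dl_min drug-likeness threshold; default 0.18.
#' @return A `candidate_set`: the retained rows plus a `provenance` column.
#' @examples
#' tab <- data.frame(herb = "H", compound = c("a", "b"),
#'                   ob = c(35, 10), dl = c(0.2, 0.05),
#'                   whitelisted = c(FALSE, TRUE))
#' screen_ingredients(tab)
#' @export
screen_ingredients <- function(table, ob_min = 30, dl_min = 0.18) {
  validate_compound_table(table)
  pass <- table$ob >= ob_min & table$dl >= dl_min
  keep <- pass | table$whitelisted
  out <- table[keep, , drop = FALSE]
  out$provenance <- ifelse(pass[keep], "threshold", "whitelist")
  rownames(out) <- NULL
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Load the packaged candidate-ingredient table
#'
#' A transcription of a published 66-compound candidate list for a classic
#' seven-herb decoction (herbs DG, GZ, SY, XX, GC, TC, DZ). The source prints
#' compound names only — no per-compound OB/DL — so the table ships as an
#' already-screened candidate set and is not re-screened.
#'
#' @return A `candidate_set` with columns herb, compound, provenance
#'   (`"fixture"`).
#' @export
load_candidate_table <- function() {
  path <- system.file("extdata", "candidate_ingredients.tsv",
                      package = "netpharm", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$provenance <- "fixture"
  class(df) <- c("candidate_set", "data.frame")
  df
}

#' Per-herb candidate counts
#'
#' @param candidates a `candidate_set` (or any data.frame with a `herb`
#'   column).
#' @param herbs optional character vector fixing the herb order (and
#'   reporting zeros for absent herbs); defaults to order of appearance.
#' @return list with `counts` (named integer vector, one entry per herb) and
#'   `total` (their sum, equal to the number of candidate records).
#' @export
count_by_herb <- function(candidates, herbs = NULL) {
  if (is.null(herbs)) herbs <- unique(candidates$herb)
  counts <- vapply(herbs, function(h) sum(candidates$herb == h), integer(1))
  names(counts) <- herbs
  list(counts = counts, total = sum(counts))
}
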