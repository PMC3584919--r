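#' Plurality vote over reciprocal partners
#'
#' Every unique reciprocal partner contributes one vote to each of its
#' full-EC annotations, no matter how many templates matched it. The
#' EC with the strictly highest vote count is predicted; a tie at the
#' top (or no voting partner) yields no prediction.
#'
#' @param query query chain id.
#' @param partners named list: partner chain id -> character vector of
#'   EC numbers (possibly empty). Duplicated partner ids are
#'   deduplicated before voting.
#' @param mode mode tag recorded on the prediction.
#' @return one-row data.frame with columns `query`, `mode`, `label`
#'   (`NA` for no prediction), `votes`, `runnerUpVotes`.
#' @examples
#' pluralityVote("3f0nA", list(`2hk3B` = "4.1.1.33"))            # 1 vote
#' pluralityVote("3f0nA", list(`2hk3B` = "4.1.1.33",
#'                             `3d4jB` = "4.1.1.33"), "M6R")     # 2 votes
#' @export
pluralityVote <- function(query, partners, mode = "6R") {
  partners <- partners[!duplicated(names(partners))]
  ecs <- unlist(partners, use.names = FALSE)
  ecs <- ecs[grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", ecs)]
  if (length(ecs) == 0L)
    return(data.frame(query = query, mode = mode, label = NA_character_,
                      votes = 0L, runnerUpVotes = 0L,
                      stringsAsFactors = FALSE))
  counts <- sort(table(ecs), decreasing = TRUE)
  top <- counts[1L]
  runner <- if (length(counts) > 1L) counts[2L] else 0L
  label <- if (sum(counts == top) > 1L) NA_character_ else names(counts)[1L]
  data.frame(query = query, mode = mode, label = label,
             votes = as.integer(top),
             runnerUpVotes = as.integer(if (is.na(label)) top else runner),
             stringsAsFactors = FALSE)
}

# classified best matches a -> b for every template of a (self pairs
# excluded upstream); one minimum-RMSD assignment per template
significantMatchesFor <- function(dataset, templatesA, a, b, model,
                                  tol = 2.5, maxRmsd = 2, cap = 1e5) {
  target <- dataset@chains[[b]]
  out <- list()
  for (tpl in templatesA) {
    found <- pdmSearch(tpl, target, tol = tol, cap = cap)
    if (length(found) == 0L) next
    found <- scoreMatches(found, tpl, target, dataset@rankings[[a]],
                          dataset@rankings[[b]])
    out <- c(out, bestMatch(found))
  }
  flagSignificant(prefilterMatches(out, maxRmsd = maxRmsd), model)
}

# template cache for a set of ids under one mode
templateSet <- function(dataset, ids, mode, useMsa = FALSE, ...) {
  tmpl <- lapply(ids, function(id) {
    msa <- if (useMsa) dataset@msas[[id]] else NULL
    makeTemplates(dataset@chains[[id]], dataset@rankings[[id]],
                  dataset@surfaces[[id]], mode = mode, msa = msa, ...)
  })
  names(tmpl) <- ids
  tmpl
}

#' Run one ETA mode end to end
#'
#' Full pipeline for one template-selection mode: pick templates for
#' every chain, search them in the other set by paired-distance
#' matching, score and filter (RMSD, SVM), keep reciprocal pairs, and
#' vote. Queries whose chains yield no template, no reciprocal
#' partner, or a tied vote are reported with `label = NA`.
#'
#' @param dataset an [EtaDataset-class].
#' @param queries,targets chain ids; default all chains for both.
#' @param mode `"6R"`, `"5R"`, `"M6R"` or `"M5R"`.
#' @param model a [MatchClassifier-class].
#' @param annotations annotation table used for voting; defaults to
#'   the dataset's. Pass a reduced table to hide query labels.
#' @param tol paired-distance tolerance in A (default 2.5).
#' @param maxRmsd prefilter RMSD cutoff in A (default 2).
#' @param cap search-node budget per template/target pair.
#' @param useMsa widen template types from the dataset's MSAs.
#' @param ... further arguments to [makeTemplates()].
#' @return list with `predictions` (data.frame, one row per query),
#'   `pairs` (reciprocal pair data.frame) and `templates`.
#' @export
runMode <- function(dataset, queries = chainIds(dataset),
                    targets = chainIds(dataset),
                    mode = c("6R", "5R", "M6R", "M5R"), model,
                    annotations = dataset@annotations, tol = 2.5,
                    maxRmsd = 2, cap = 1e5, useMsa = FALSE, ...) {
  mode <- match.arg(mode)
  ids <- union(queries, targets)
  tmpl <- templateSet(dataset, ids, mode, useMsa = useMsa, ...)
  annotations <- fullEcOnly(annotations)
  matchCache <- new.env(parent = emptyenv())
  getMatches <- function(a, b) {
    key <- paste0(a, "->", b)
    if (is.null(matchCache[[key]]))
      matchCache[[key]] <- significantMatchesFor(dataset, tmpl[[a]], a, b,
                                                 model, tol, maxRmsd, cap)
    matchCache[[key]]
  }
  preds <- list()
  pairRows <- list()
  for (q in queries) {
    fwd <- list(); rev <- list()
    for (t in setdiff(targets, q)) {
      fwd <- c(fwd, getMatches(q, t))
      rev <- c(rev, getMatches(t, q))
    }
    rec <- reciprocalMatches(fwd, rev)
    partnersIds <- setdiff(unique(c(rec$a, rec$b)), q)
    partners <- lapply(partnersIds, function(p) ecOf(annotations, p))
    names(partners) <- partnersIds
    preds[[q]] <- pluralityVote(q, partners, mode = mode)
    if (nrow(rec)) pairRows[[q]] <- cbind(queryOfRecord = q, rec)
  }
  list(predictions = do.call(rbind, c(preds, make.row.names = FALSE)),
       pairs = if (length(pairRows))
         do.call(rbind, c(pairRows, make.row.names = FALSE))
       else NULL,
       templates = tmpl)
}

#' Combine per-mode predictions iteratively
#'
#' For each query, the first mode in `order` that produced a
#' prediction supplies the label; remaining modes are consulted only
#' for queries still unannotated. The combined coverage is therefore
#' at least that of each individual mode. The conventional order is
#' by decreasing stand-alone accuracy, 6R, 5R, M6R, M5R.
#'
#' @param predictionsByMode named list of prediction data.frames as
#'   returned in `runMode()$predictions`.
#' @param order modes to apply, first wins (default
#'   `c("6R","5R","M6R","M5R")` restricted to those present).
#' @return data.frame of combined predictions, `mode = "ALL"`, with a
#'   `sourceMode` column recording which mode supplied each label.
#' @export
iterativeCombine <- function(predictionsByMode,
                             order = c("6R", "5R", "M6R", "M5R")) {
  order <- order[order %in% names(predictionsByMode)]
  if (length(order) == 0L) stop("no predictions to combine")
  queries <- unique(unlist(lapply(predictionsByMode[order],
                                  function(p) p$query)))
  rows <- lapply(queries, function(q) {
    for (m in order) {
      p <- predictionsByMode[[m]]
      row <- p[p$query == q, , drop = FALSE]
      if (nrow(row) == 1L && !is.na(row$label)) {
        row$sourceMode <- m
        row$mode <- "ALL"
        return(row)
      }
    }
    data.frame(query = q, mode = "ALL", label = NA_character_,
               votes = 0L, runnerUpVotes = 0L,
               sourceMode = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write / read the match report TSV
#'
#' One row per match: query, target, mode tag, template and matched
#' positions (comma-joined), rmsd, ETScore, per-position rank
#' differences and the significance flag.
#'
#' @param matches list of [TemplateMatch-class].
#' @param modeTag mode tag to record.
#' @param path output file.
#' @return the data.frame written, invisibly.
#' @export
writeMatchReport <- function(matches, modeTag, path) {
  df <- data.frame(
    query = vapply(matches, function(m) m@queryChain, character(1)),
    target = vapply(matches, function(m) m@targetChain, character(1)),
    mode = modeTag,
    positions = vapply(matches, function(m)
      paste(m@templatePositions, collapse = ","), character(1)),
    matched = vapply(matches, function(m)
      paste(m@matchedPositions, collapse = ","), character(1)),
    rmsd = vapply(matches, function(m) m@rmsd, numeric(1)),
    etScore = vapply(matches, function(m) m@etScore, numeric(1)),
    rankDiffs = vapply(matches, function(m)
      paste(signif(m@rankDiffs, 6), collapse = ","), character(1)),
    significant = vapply(matches, function(m) m@significant, logical(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
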