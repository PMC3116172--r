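# Structure-activity suggestion engine: enumerate single-point R-group
# mutations observed elsewhere in the series, score each hypothetical
# molecule by its predicted activity gain over the average input compound,
# weight it by structural support, and rank.

mutation_label <- function(old_name, new_name, position) {
  if (old_name == "methyl" && new_name == "H")
    sprintf("demethylation at position %s", position)
  else if (old_name == "H" && new_name == "methyl")
    sprintf("methylation at position %s", position)
  else if (old_name == "H" && new_name == "hydroxyl")
    sprintf("hydroxylation at position %s", position)
  else if (old_name == "hydroxyl" && new_name == "H")
    sprintf("dehydroxylation at position %s", position)
  else
    sprintf("%s -> %s at position %s", old_name, new_name, position)
}

#' Enumerate single-point chimeric molecules
#'
#' For every matched molecule, every scaffold position, and every R-group
#' observed at that position in another molecule of the same scaffold that
#' differs from the parent's group, one hypothetical molecule is formed.
#' The list is deduplicated by the full (scaffold, position -> R-group)
#' map, and chimeras identical to an existing input molecule are removed.
#'
#' @param matchset A `bq_matchset` from [match_scaffolds()].
#' @param scaffolds The scaffold list used for matching.
#' @return List of chimera entries: each holds the assembled `bq_mol`, the
#'   scaffold, the full R-group map, and `generators` — every
#'   (parent, position, old, new) single-point route that produces this
#'   molecule (the first route also populates the top-level parent/
#'   position/old/new/mutation fields).
#' @export
enumerate_chimeras <- function(matchset, scaffolds) {
  if (!length(matchset$matches)) stop("no scaffold matches", call. = FALSE)
  sc_by_id <- stats::setNames(scaffolds, vapply(scaffolds, `[[`, "", "id"))
  # observed fragment exemplars per (scaffold, position, key)
  observed <- list()
  for (m in matchset$matches) {
    for (lab in names(m$rgroups)) {
      key <- fragment_key(m$rgroups[[lab]])
      slot <- paste(m$scaffold, lab, key, sep = "\r")
      if (is.null(observed[[slot]]))
        observed[[slot]] <- list(frag = m$rgroups[[lab]], n = 0L)
      observed[[slot]]$n <- observed[[slot]]$n + 1L
    }
  }
  input_maps <- vapply(matchset$matches, function(m)
    paste(m$scaffold,
          paste(vapply(m$rgroups, fragment_key, ""), collapse = "\r"),
          sep = "\r"), "")
  chimeras <- list()
  for (m in matchset$matches) {
    sc <- sc_by_id[[m$scaffold]]
    keys <- vapply(m$rgroups, fragment_key, "")
    for (lab in names(m$rgroups)) {
      slots <- grep(paste0("^", m$scaffold, "\r", lab, "\r"), names(observed),
                    value = TRUE, fixed = FALSE)
      for (slot in slots) {
        key <- sub(".*\r", "", slot)
        if (key == keys[[lab]]) next
        # observed in >= 1 other molecule: any holder differs from the
        # parent because the parent carries a different key here
        newmap <- keys; newmap[[lab]] <- key
        sig <- paste(m$scaffold, paste(newmap, collapse = "\r"), sep = "\r")
        if (sig %in% input_maps) next
        old_name <- fragment_name(m$rgroups[[lab]])
        new_name <- fragment_name(observed[[slot]]$frag)
        generator <- list(parent = m$id, position = lab,
                          old = old_name, new = new_name,
                          mutation = mutation_label(old_name, new_name, lab))
        if (!is.null(chimeras[[sig]])) {
          # same hypothetical molecule reached by another single-point
          # route: keep it once, remember every generating route
          chimeras[[sig]]$generators <- c(chimeras[[sig]]$generators,
                                          list(generator))
          next
        }
        rg <- m$rgroups
        rg[[lab]] <- observed[[slot]]$frag
        mol <- reassemble(sc, rg,
                          id = sprintf("%s|%s:%s->%s", m$id, lab, old_name, new_name))
        chimeras[[sig]] <- c(list(molecule = mol, scaffold = m$scaffold,
                                  rgroups = rg, generators = list(generator)),
                             generator)
      }
    }
  }
  unname(chimeras)
}

#' Activity-gain score of a chimera
#'
#' The score is the model's predicted probability of activity for the
#' hypothetical molecule minus the mean predicted probability over the
#' input library, so 0 means "as likely active as an average input
#' molecule" and positive values are more promising. The printed percentage
#' gain is 100 x score.
#'
#' @param model A `bq_bayes` model.
#' @param chimera_desc Descriptor vector of the chimera (same set the model
#'   was trained on).
#' @param library_mean_p Mean predicted P(active) over the input library.
#' @return Numeric score.
#' @export
score_chimera <- function(model, chimera_desc, library_mean_p) {
  predict_bayes(model, chimera_desc) - library_mean_p
}

#' Structural-support weight of a chimera
#'
#' Cumulative similarity to the same-scaffold input molecules: the mean,
#' over those molecules, of the fraction of scaffold positions carrying an
#' identical R-group. Lies in \[0, 1\]; higher means a larger statistical
#' base behind the suggestion.
#'
#' @param chimera A chimera entry from [enumerate_chimeras()].
#' @param matchset The `bq_matchset` of the input library.
#' @return Numeric weight in \[0, 1\].
#' @export
weight_chimera <- function(chimera, matchset) {
  peers <- Filter(function(m) m$scaffold == chimera$scaffold, matchset$matches)
  if (!length(peers)) return(0)
  ckeys <- vapply(chimera$rgroups, fragment_key, "")
  sims <- vapply(peers, function(m) {
    mkeys <- vapply(m$rgroups, fragment_key, "")
    mean(ckeys == mkeys[names(ckeys)])
  }, 0)
  mean(sims)
}

#' Build the ranked suggestion table
#'
#' Matches the library against the scaffolds, enumerates single-point
#' chimeras, scores each with the binary Bayes model (activity gain over
#' the average input molecule), weights by structural support, and ranks by
#' score x weight (ties: higher weight first, then parent id). Unmatched
#' library compounds contribute to the probability baseline but not to
#' enumeration.
#'
#' @param model A `bq_bayes` model trained on `descriptor_set` descriptors
#'   for the target cell line.
#' @param library A `bq_library`.
#' @param scaffolds List of `bq_scaffold` in priority order.
#' @param top_n Number of suggestions to keep (default 10; 0 gives an
#'   empty table).
#' @param descriptor_set Descriptor set used for scoring (must match the
#'   model's training set).
#' @param matchset Optional precomputed `bq_matchset`.
#' @return A `bq_sar_report` data frame: rank, parent, scaffold, position,
#'   old/new R-group, mutation label, score, percentage gain, weight and
#'   the ranking key. Chimeras whose descriptor computation fails are
#'   dropped with a warning.
#' @export
build_sar_report <- function(model, library, scaffolds, top_n = 10L,
                             descriptor_set = "general", matchset = NULL) {
  if (is.null(matchset)) matchset <- match_scaffolds(library, scaffolds)
  desc_fun <- if (descriptor_set == "general") compute_general_descriptors
              else compute_drug_like_index
  empty <- data.frame(rank = integer(), parent = character(),
                      scaffold = character(), position = character(),
                      old = character(), new = character(),
                      mutation = character(), score = numeric(),
                      pct_gain = numeric(), weight = numeric(),
                      ranking = numeric())
  if (!length(matchset$matches)) {
    attr(empty, "notice") <- "no scaffold matches"
    return(structure(empty, class = c("bq_sar_report", "data.frame")))
  }
  chimeras <- enumerate_chimeras(matchset, scaffolds)
  if (!length(chimeras)) {
    attr(empty, "notice") <- "no novel chimeras could be enumerated"
    return(structure(empty, class = c("bq_sar_report", "data.frame")))
  }
  lib_desc <- t(vapply(library$records, function(r) desc_fun(r$molecule),
                       desc_fun(library$records[[1]]$molecule)))
  lib_p <- predict_bayes(model, lib_desc)
  names(lib_p) <- library_ids(library)
  library_mean_p <- mean(lib_p)
  rows <- list()
  for (ch in chimeras) {
    d <- tryCatch(desc_fun(ch$molecule), error = function(e) NULL)
    if (is.null(d)) {
      warning("descriptor computation failed for chimera of ", ch$parent,
              "; suggestion dropped", call. = FALSE)
      next
    }
    p_ch <- predict_bayes(model, d)
    s <- p_ch - library_mean_p
    w <- weight_chimera(ch, matchset)
    # when several single-point routes produce this molecule, attribute it
    # to the route with the largest predicted activity gain over its
    # parent: the modification responsible for the improvement
    gains <- vapply(ch$generators, function(g) p_ch - lib_p[[g$parent]], 0)
    gen <- ch$generators[[which.max(gains)]]
    rows[[length(rows) + 1L]] <- data.frame(
      parent = gen$parent, scaffold = ch$scaffold, position = gen$position,
      old = gen$old, new = gen$new, mutation = gen$mutation,
      score = s, pct_gain = 100 * s, weight = w, ranking = s * w)
  }
  if (!length(rows)) {
    attr(empty, "notice") <- "all chimeras dropped"
    return(structure(empty, class = c("bq_sar_report", "data.frame")))
  }
  df <- do.call(rbind, rows)
  df <- df[order(-df$ranking, -df$weight, df$parent), , drop = FALSE]
  df <- utils::head(df, n = max(0L, as.integer(top_n)))
  if (nrow(df)) df <- cbind(rank = seq_len(nrow(df)), df)
  else df <- empty
  rownames(df) <- NULL
  structure(df, class = c("bq_sar_report", "data.frame"))
}

#' @export
print.bq_sar_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("empty suggestion table",
        if (!is.null(attr(x, "notice"))) paste0(" (", attr(x, "notice"), ")"), "\n")
    return(invisible(x))
  }
  df <- as.data.frame(x)
  df$score <- sprintf("%+.1f%%", df$pct_gain)
  df$weight <- sprintf("[%.2f]", df$weight)
  print(df[, c("rank", "parent", "mutation", "score", "weight")],
        row.names = FALSE)
  invisible(x)
}
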