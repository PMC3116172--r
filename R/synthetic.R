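# Synthetic compound-library generator. Emulates the statistical structure
# of a 93-compound natural-product derivative series assayed against four
# cell lines: four saturated polycyclic scaffolds with substituent
# positions, a handful of off-scaffold decoys, and an additive activity
# model on log10 IC50 in which exactly one cell line carries a
# descriptor-expressible structure-activity signal while the others are
# noise-dominated (non-specific cytotoxicity).
#
# Position semantics mirror the three modification routes of interest:
#   position 8  — a ring-nitrogen methylation site (N-H vs N-CH3);
#                 demethylation is the strongest activity improver
#   position 7  — a ring-carbon alkyl site; methylation improves mildly
#   position 11 — a ring-carbon oxygenation site; hydroxylation improves
#   position 3  — a neutral halogenation site (no activity effect)
# Placing the methylation signal on a nitrogen makes position 8 chemically
# distinct from position 7, so additive physicochemical descriptors can
# resolve which position a methyl sits on. The position vocabularies span
# ~189 R-group combinations, well above the library size, so single-point
# mutation enumeration yields a genuine pool of novel hypothetical
# molecules.

.ring_edges <- function(idx) {
  k <- length(idx)
  data.frame(a1 = idx, a2 = idx[c(2:k, 1)], order = 1L)
}

.carbon_atoms <- function(n) data.frame(element = rep("C", n), charge = 0L,
                                        aromatic = FALSE)

#' The generator's four scaffolds
#'
#' S1: three linearly fused six-membered rings with a ring nitrogen
#' (positions 7, 8, 11); S2: two fused six-membered rings with a ring
#' nitrogen (positions 7, 8); S3: fused 6-5 system with the nitrogen in
#' the five-membered ring (positions 8, 11); S4: two six-membered
#' carbocycles joined by a single bond (positions 7, 11). Listed in
#' matching priority order (largest first).
#'
#' @return List of four `bq_scaffold` objects.
#' @export
default_scaffolds <- function() {
  mk <- function(id, n, nitrogen, edges, positions) {
    atoms <- .carbon_atoms(n)
    if (!is.na(nitrogen)) atoms$element[nitrogen] <- "N"
    scaffold(id, atoms, edges, positions)
  }
  s1 <- mk("S1", 14L, 8L,
           rbind(.ring_edges(1:6),
                 data.frame(a1 = c(5, 7, 8, 9, 10), a2 = c(7, 8, 9, 10, 6), order = 1L),
                 data.frame(a1 = c(9, 11, 12, 13, 14), a2 = c(11, 12, 13, 14, 10), order = 1L)),
           c("3" = 3L, "7" = 7L, "8" = 8L, "11" = 11L))
  s2 <- mk("S2", 10L, 8L,
           rbind(.ring_edges(1:6),
                 data.frame(a1 = c(5, 7, 8, 9, 10), a2 = c(7, 8, 9, 10, 6), order = 1L)),
           c("3" = 3L, "7" = 7L, "8" = 8L, "11" = 10L))
  s3 <- mk("S3", 9L, 8L,
           rbind(.ring_edges(1:6),
                 data.frame(a1 = c(5, 7, 8, 9), a2 = c(7, 8, 9, 6), order = 1L)),
           c("3" = 2L, "7" = 7L, "8" = 8L, "11" = 3L))
  # S4 carries no ring nitrogen and uses its own position numbering; its
  # substituents never enter the activity model (a pure diversity scaffold)
  s4 <- mk("S4", 12L, NA,
           rbind(.ring_edges(1:6), .ring_edges(7:12),
                 data.frame(a1 = 1L, a2 = 7L, order = 1L)),
           c("3" = 2L, "4" = 4L, "12" = 10L))
  list(s1, s2, s3, s4)
}

.atom_frag <- function(el) {
  list(atoms = data.frame(element = el, charge = 0L, aromatic = FALSE),
       bonds = data.frame(a1 = integer(), a2 = integer(), order = integer()),
       attach = 1L)
}

.fragment_for <- function(name) {
  switch(name,
    H = NULL,
    methyl = .atom_frag("C"),
    hydroxyl = .atom_frag("O"),
    fluoro = .atom_frag("F"),
    chloro = .atom_frag("Cl"),
    ethyl = list(atoms = data.frame(element = c("C", "C"), charge = 0L,
                                    aromatic = FALSE),
                 bonds = data.frame(a1 = 1L, a2 = 2L, order = 1L),
                 attach = 1L),
    methoxy = list(atoms = data.frame(element = c("O", "C"), charge = 0L,
                                      aromatic = FALSE),
                   bonds = data.frame(a1 = 1L, a2 = 2L, order = 1L),
                   attach = 1L),
    stop("unknown R-group name: ", name))
}

#' Generator configuration
#'
#' Defaults encode the emulated study conditions: 93 compounds over 4
#' scaffolds plus 6 off-scaffold decoys, four cell lines with the
#' positive-control IC50 cutoffs 38.11 / 9.13 / 61.05 / 58.33 ug/mL, one
#' signal cell line (NCI-H446 analogue) whose log10 IC50 is dominated by
#' the R-group coefficients (demethylation at 8 > hydroxylation at 11 >
#' methylation at 7, noise sd 0.12), and three noise-dominated cell lines
#' (zero coefficients, noise sd 0.45, baseline at the cutoff so labels are
#' near-balanced).
#'
#' @param n_compounds Library size (default 93).
#' @param n_off_scaffold Number of acyclic decoys matching no scaffold
#'   (default 6).
#' @param noise_sd Per-cell-line noise standard deviation on log10 IC50.
#' @param baseline Per-cell-line baseline log10 IC50.
#' @param cutoffs Per-cell-line IC50 cutoffs (ug/mL).
#' @param scaffold_probs Sampling probabilities of the four scaffolds.
#' @param rgroup_probs Per-position R-group sampling probabilities.
#' @param effects Per-cell-line, per-position, per-R-group additive
#'   coefficients on log10 IC50.
#' @return A `bq_genconfig` list.
#' @export
generator_config <- function(n_compounds = 93L,
                             n_off_scaffold = 6L,
                             noise_sd = c("BxPC-3" = 0.45, "NCI-H446" = 0.12,
                                          "SW1990" = 0.45, "NCI-H157" = 0.45),
                             baseline = c("BxPC-3" = log10(38.11),
                                          "NCI-H446" = log10(9.13) + 0.15,
                                          "SW1990" = log10(61.05),
                                          "NCI-H157" = log10(58.33)),
                             cutoffs = c("BxPC-3" = 38.11, "NCI-H446" = 9.13,
                                         "SW1990" = 61.05, "NCI-H157" = 58.33),
                             scaffold_probs = c(S1 = 0.34, S2 = 0.27,
                                                S3 = 0.21, S4 = 0.18),
                             rgroup_probs = list(
                               "3" = c(H = 0.60, fluoro = 0.40),
                               "7" = c(H = 0.60, methyl = 0.40),
                               "8" = c(H = 0.30, methyl = 0.70),
                               "11" = c(H = 0.55, hydroxyl = 0.45),
                               "4" = c(H = 0.55, methyl = 0.25, ethyl = 0.20),
                               "12" = c(H = 0.50, hydroxyl = 0.30, methoxy = 0.20)),
                             effects = list("NCI-H446" = list(
                               "7" = c(H = 0.10, methyl = -0.10),
                               "8" = c(H = -0.75, methyl = 0.45),
                               "11" = c(H = 0.15, hydroxyl = -0.15)))) {
  stopifnot(n_off_scaffold < n_compounds, all(noise_sd >= 0),
            all(cutoffs > 0))
  cells <- names(cutoffs)
  stopifnot(identical(names(noise_sd), cells), identical(names(baseline), cells))
  structure(list(n_compounds = as.integer(n_compounds),
                 n_off_scaffold = as.integer(n_off_scaffold),
                 cell_lines = cells, noise_sd = noise_sd, baseline = baseline,
                 cutoffs = cutoffs, scaffold_probs = scaffold_probs,
                 rgroup_probs = rgroup_probs, effects = effects),
            class = "bq_genconfig")
}

# random acyclic branched alkane/alcohol decoy (never matches a ring scaffold)
.random_decoy <- function(id) {
  nc <- sample(6:10, 1L)
  atoms <- .carbon_atoms(nc)
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  for (i in 2:nc)
    bonds <- rbind(bonds, data.frame(a1 = sample(seq_len(i - 1L), 1L), a2 = i,
                                     order = 1L))
  for (k in seq_len(sample(0:2, 1L))) {
    atoms <- rbind(atoms, data.frame(element = "O", charge = 0L, aromatic = FALSE))
    bonds <- rbind(bonds, data.frame(a1 = sample(seq_len(nc), 1L),
                                     a2 = nrow(atoms), order = 1L))
  }
  molecule(id, atoms, bonds)
}

#' Generate a synthetic compound library with known ground truth
#'
#' Deterministic given `seed`. Scaffold compounds are cores with randomly
#' assigned R-groups; decoys are random acyclic molecules. For every cell
#' line, log10 IC50 = baseline + sum of position/R-group coefficients +
#' Gaussian noise; decoys and signal-free cell lines receive the noise
#' model only.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return List with `library` (a `bq_library`), `truth` (per-compound
#'   true mean log10 IC50 and true labels at the cutoffs, plus the
#'   generating coefficients), and `scaffolds`.
#' @export
generate_library <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "bq_genconfig"))
  set.seed(as.integer(seed))
  scaffolds <- default_scaffolds()
  sc_by_id <- stats::setNames(scaffolds, vapply(scaffolds, `[[`, "", "id"))
  n <- config$n_compounds
  decoy_idx <- sort(sample(seq_len(n), config$n_off_scaffold))
  cells <- config$cell_lines
  mols <- vector("list", n)
  truth <- data.frame(id = sprintf("cpd_%03d", seq_len(n)),
                      scaffold = NA_character_,
                      r3 = NA_character_, r7 = NA_character_,
                      r8 = NA_character_, r11 = NA_character_,
                      r4 = NA_character_, r12 = NA_character_,
                      stringsAsFactors = FALSE)
  mean_log <- matrix(0, n, length(cells), dimnames = list(truth$id, cells))
  for (i in seq_len(n)) {
    id <- truth$id[i]
    if (i %in% decoy_idx) {
      mols[[i]] <- .random_decoy(id)
      truth$scaffold[i] <- "none"
      effs <- stats::setNames(rep(0, length(cells)), cells)
    } else {
      sid <- sample(names(config$scaffold_probs), 1L, prob = config$scaffold_probs)
      sc <- sc_by_id[[sid]]
      truth$scaffold[i] <- sid
      rg <- list(); effs <- stats::setNames(rep(0, length(cells)), cells)
      for (lab in names(sc$positions)) {
        probs <- config$rgroup_probs[[lab]]
        if (is.null(probs)) next
        gname <- sample(names(probs), 1L, prob = probs)
        rg[[lab]] <- .fragment_for(gname)
        truth[[paste0("r", lab)]][i] <- gname
        for (cl in cells) {
          co <- config$effects[[cl]][[lab]]
          if (!is.null(co) && gname %in% names(co))
            effs[cl] <- effs[cl] + co[[gname]]
        }
      }
      mols[[i]] <- reassemble(sc, rg, id = id)
    }
    mean_log[i, ] <- config$baseline[cells] + effs[cells]
  }
  noise <- vapply(cells, function(cl) stats::rnorm(n, 0, config$noise_sd[[cl]]),
                  numeric(n))
  ic50 <- 10^(mean_log + noise)
  lib <- join_library(mols, ic50)
  true_labels <- sweep(mean_log, 2, log10(config$cutoffs[cells]), "<=")
  list(library = lib,
       truth = list(table = truth, mean_log10_ic50 = mean_log,
                    true_labels = true_labels, effects = config$effects,
                    config = config, seed = as.integer(seed)),
       scaffolds = scaffolds)
}

#' Export a generated library as a plain-text fixture directory
#'
#' Writes `structures.sdf`, `activities.csv`, `truth.csv` and a
#' `config.txt` key-value echo; re-reading the structures and activities
#' reproduces the library.
#'
#' @param gen Result of [generate_library()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
export_fixture <- function(gen, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_structures(gen$library, file.path(dir, "structures.sdf"))
  am <- activity_matrix(gen$library)
  utils::write.csv(data.frame(id = rownames(am), am, check.names = FALSE),
                   file.path(dir, "activities.csv"), row.names = FALSE, na = "")
  tr <- cbind(gen$truth$table,
              stats::setNames(as.data.frame(gen$truth$mean_log10_ic50),
                              paste0("mean_log10_", colnames(gen$truth$mean_log10_ic50))),
              stats::setNames(as.data.frame(gen$truth$true_labels),
                              paste0("active_", colnames(gen$truth$true_labels))))
  utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- gen$truth$config
  kv <- c(sprintf("n_compounds=%d", cfg$n_compounds),
          sprintf("n_off_scaffold=%d", cfg$n_off_scaffold),
          sprintf("seed=%d", gen$truth$seed),
          sprintf("cell_lines=%s", paste(cfg$cell_lines, collapse = ",")),
          sprintf("cutoffs=%s", paste(cfg$cutoffs, collapse = ",")),
          sprintf("noise_sd=%s", paste(cfg$noise_sd, collapse = ",")),
          sprintf("baseline=%s", paste(round(cfg$baseline, 6), collapse = ",")))
  for (cl in names(cfg$effects)) for (p in names(cfg$effects[[cl]]))
    kv <- c(kv, sprintf("effect.%s.%s=%s", cl, p,
                        paste(names(cfg$effects[[cl]][[p]]),
                              cfg$effects[[cl]][[p]], sep = ":", collapse = ",")))
  writeLines(kv, file.path(dir, "config.txt"))
  invisible(dir)
}
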