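# Toy molecules and tiny file fixtures built in code.

mol_methane <- function() molecule("methane", data.frame(element = "C"))

mol_ethane <- function()
  molecule("ethane", data.frame(element = c("C", "C")),
           data.frame(a1 = 1L, a2 = 2L, order = 1L))

mol_propane <- function()
  molecule("propane", data.frame(element = c("C", "C", "C")),
           data.frame(a1 = c(1L, 2L), a2 = c(2L, 3L), order = 1L))

# Kekule benzene; aromatic flags derived by perception.
mol_benzene <- function() {
  m <- molecule("benzene", data.frame(element = rep("C", 6)),
                data.frame(a1 = 1:6, a2 = c(2:6, 1L),
                           order = c(2L, 1L, 2L, 1L, 2L, 1L)))
  mol_perceive_aromatic_public(m)
}

# wrapper because perception is internal to the package namespace
mol_perceive_aromatic_public <- function(m)
  getFromNamespace("mol_perceive_aromatic", "bqsar")(m)

mol_biphenyl <- function() {
  m <- molecule("biphenyl", data.frame(element = rep("C", 12)),
                rbind(data.frame(a1 = 1:6, a2 = c(2:6, 1L),
                                 order = c(2L, 1L, 2L, 1L, 2L, 1L)),
                      data.frame(a1 = 7:12, a2 = c(8:12, 7L),
                                 order = c(2L, 1L, 2L, 1L, 2L, 1L)),
                      data.frame(a1 = 1L, a2 = 7L, order = 1L)))
  mol_perceive_aromatic_public(m)
}

# a simple cyclohexane-core toy scaffold with two positions
toy_scaffold <- function(id = "T", positions = c("1" = 1L, "4" = 4L)) {
  scaffold(id, data.frame(element = rep("C", 6)),
           data.frame(a1 = 1:6, a2 = c(2:6, 1L), order = 1L),
           positions)
}

frag_named <- function(name)
  getFromNamespace(".fragment_for", "bqsar")(name)

fragment_key_public <- function(f)
  getFromNamespace("fragment_key", "bqsar")(f)

toy_compound <- function(id, sc, rg) reassemble(sc, rg, id = id)

write_activity_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# SDF text with 3 records, the middle one malformed (truncated atom block)
write_bad_sdf <- function(path = tempfile(fileext = ".sdf")) {
  good <- function(id) paste(c(
    id, "  fixture", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "M  END", "$$$$"), collapse = "\n")
  bad <- paste(c("broken", "  fixture", "",
                 "  5  4  0  0  0  0  0  0  0  0999 V2000",
                 "    0.0000    0.0000    0.0000 C   0  0",
                 "M  END", "$$$$"), collapse = "\n")
  writeLines(c(good("m1"), bad, good("m3")), path)
  path
}

random_molecule <- function(id, n = 8L) {
  els <- sample(c("C", "C", "C", "N", "O"), n, replace = TRUE)
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  for (i in 2:n)
    bonds <- rbind(bonds, data.frame(a1 = sample(seq_len(i - 1L), 1L),
                                     a2 = i, order = 1L))
  # occasionally close a ring
  if (stats::runif(1) < 0.5 && n >= 4L)
    bonds <- rbind(bonds, data.frame(a1 = 1L, a2 = n, order = 1L))
  molecule(id, data.frame(element = els), bonds)
}

permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  atoms <- mol$atoms[inv, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  bonds$a1 <- perm[bonds$a1]
  bonds$a2 <- perm[bonds$a2]
  molecule(mol$id, atoms, bonds)
}
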