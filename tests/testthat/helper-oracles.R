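# shared helpers: independent small oracles used across test files

# direct least-squares oracle (QR), independent of the Gauss-Seidel path
ls_oracle <- function(G, y) {
  qr.coef(qr(G), y)
}

# independent flood-fill component count on a cp_mol
flood_fill_components <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 0) return(0L)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (b in seq_len(nrow(mol$bonds))) {
    a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
    adj[[a1]] <- c(adj[[a1]], a2)
    adj[[a2]] <- c(adj[[a2]], a1)
  }
  seen <- logical(n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, adj[[v]][!seen[adj[[v]]]])
    }
  }
  comps
}

# group multiset as a sorted label, for permutation-invariance checks
group_multiset <- function(smiles) {
  counts <- perceive_groups(parse_smiles(smiles))
  paste(sort(paste(counts$key, counts$count)), collapse = ";")
}

# minimal hand-built 3D SDF text (explicit hydrogens optional)
make_sdf3d <- function(elements, coords, bonds, charges = NULL, name = "test") {
  lines <- c(name, "  test", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     length(elements), nrow(bonds)))
  for (i in seq_along(elements)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      coords[i, 1], coords[i, 2], coords[i, 3], elements[i]))
  }
  for (b in seq_len(nrow(bonds))) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              bonds[b, 1], bonds[b, 2], bonds[b, 3]))
  }
  if (!is.null(charges)) {
    for (i in seq_along(charges)) {
      if (charges[i] != 0) {
        lines <- c(lines, sprintf("M  CHG  1%4d%4d", i, charges[i]))
      }
    }
  }
  c(lines, "M  END", "$$$$")
}

read_sdf_text <- function(lines) {
  path <- tempfile(fileext = ".sdf")
  writeLines(lines, path)
  on.exit(unlink(path))
  read_sdf(path)
}
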