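# Molecular structure model -------------------------------------------------
#
# A `cp_mol` is a light container built on top of the structures returned by
# ChemmineR/OpenBabel: a tibble of heavy atoms, a tibble of bonds, and the
# perception state (ring membership, aromatic flags, components) that the
# group-notation rules need.  Explicit hydrogens are folded into per-atom
# hydrogen counts; their coordinates are kept separately so that geometric
# specials (hydrogen bridges) can still be evaluated on 3D inputs.

SUPPORTED_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")

#' Parse SMILES into molecule objects
#'
#' Converts SMILES strings (one molecule each, `.`-separated components allowed
#' for salts and ion pairs) into `cp_mol` objects.  Conversion to a connection
#' table is delegated to OpenBabel; aromatic input is kekulized and aromaticity
#' is then re-perceived under the conventions of the group notation (benzenoid
#' six-membered rings; 1,3-dialkylimidazolium normalised with the positive
#' charge on C2).  No 3D coordinates are produced, so geometry-dependent
#' special groups fall back to their topological estimates.
#'
#' @param smiles character vector of SMILES strings.
#' @param name optional names (defaults to the SMILES text).
#' @return A list of `cp_mol` objects (a single object if `length(smiles) == 1`).
#' @examples
#' mol <- parse_smiles("CCO")
#' mol$atoms
#' @export
parse_smiles <- function(smiles, name = smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  name <- rep_len(name, length(smiles))
  mols <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(smiles[[i]])),
      error = function(e) stop("invalid SMILES '", smiles[[i]], "': ",
                               conditionMessage(e), call. = FALSE)
    )
    mol <- mol_from_sdf(sdf[[1]], name = name[[i]], chg = NULL)
    if (nrow(mol$atoms) == 0) {
      stop("invalid SMILES '", smiles[[i]], "': no atoms perceived", call. = FALSE)
    }
    mols[[i]] <- mol
  }
  if (length(mols) == 1) mols[[1]] else mols
}

#' Read molecules from an SDF/MOL (V2000) file
#'
#' Records are parsed with ChemmineR; `M  CHG` property lines (which ChemmineR
#' does not retain) are recovered from the raw record text so that formal
#' charges survive.  A malformed record is reported with its index and skipped;
#' parsing continues with the remaining records.
#'
#' @param path path to an SDF or MOL file.
#' @return A list of `cp_mol` objects (possibly empty).
#' @export
read_sdf <- function(path) {
  stopifnot(file.exists(path))
  txt <- readLines(path, warn = FALSE)
  if (length(trimws(txt)) == 0 || all(!nzchar(trimws(txt)))) return(list())
  sdfset <- tryCatch(ChemmineR::read.SDFset(path),
                     error = function(e) stop("cannot read SDF: ",
                                              conditionMessage(e), call. = FALSE))
  # per-record M CHG lines from the raw text
  rec_end <- grep("^\\$\\$\\$\\$", txt)
  if (length(rec_end) == 0) rec_end <- length(txt)
  rec_start <- c(1, utils::head(rec_end, -1) + 1)
  chg_by_rec <- lapply(seq_along(rec_start), function(r) {
    block <- txt[rec_start[r]:rec_end[r]]
    parse_chg_lines(block[grepl("^M  CHG", block)])
  })
  mols <- list()
  for (r in seq_along(sdfset)) {
    mol <- tryCatch(
      mol_from_sdf(sdfset[[r]], name = ChemmineR::sdfid(sdfset[r]),
                   chg = if (r <= length(chg_by_rec)) chg_by_rec[[r]] else NULL),
      error = function(e) {
        warning("SDF record ", r, " skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    if (!is.null(mol)) mols[[length(mols) + 1]] <- mol
  }
  mols
}

parse_chg_lines <- function(lines) {
  if (length(lines) == 0) return(NULL)
  out <- integer(0)
  for (ln in lines) {
    flds <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    n <- flds[1]
    for (k in seq_len(n)) out[as.character(flds[2 * k])] <- flds[2 * k + 1]
  }
  out
}

# old-style atom-block charge codes (1..3 = +3..+1, 5..7 = -1..-3)
charge_from_code <- function(code) {
  ifelse(code %in% 1:3, 4L - as.integer(code),
         ifelse(code %in% 5:7, 4L - as.integer(code), 0L))
}

mol_from_sdf <- function(sdf, name = "", chg = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  counts <- ChemmineR::header(sdf)[["Counts_Line"]]
  has_3d <- isTRUE(grepl("3D", counts)) ||
    (nrow(ab) > 0 && ncol(ab) >= 3 && any(abs(ab[, 3]) > 1e-6))
  element <- sub("_.*$", "", rownames(ab))
  charge <- charge_from_code(ab[, "C6"])
  if (!is.null(chg)) {            # M CHG supersedes atom-block codes
    charge <- rep(0L, length(element))
    charge[as.integer(names(chg))] <- unname(chg)
  }
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  build_mol(element = element, charge = as.integer(charge),
            coords = ab[, 1:3, drop = FALSE], bonds = bonds,
            name = as.character(name)[1], has_3d = has_3d)
}

build_mol <- function(element, charge, coords, bonds, name = "", has_3d = FALSE) {
  bad <- setdiff(unique(element), SUPPORTED_ELEMENTS)
  if (length(bad) > 0) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(bonds$order > 3)) {
    stop("aromatic/query bond orders are not supported; supply a kekulized ",
         "connection table", call. = FALSE)
  }
  n <- length(element)
  if (nrow(bonds) > 0 && (max(bonds$a1, bonds$a2) > n || min(bonds$a1, bonds$a2) < 1)) {
    stop("bond references a non-existent atom", call. = FALSE)
  }

  # fold explicit hydrogens into neighbour H counts (keep their coordinates)
  is_h <- element == "H"
  expl_h <- rep(0L, n)
  h_coord <- NULL
  if (any(is_h)) {
    for (b in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[b]; a2 <- bonds$a2[b]
      if (is_h[a1] && is_h[a2]) next
      if (is_h[a1] || is_h[a2]) {
        heavy <- if (is_h[a1]) a2 else a1
        h <- if (is_h[a1]) a1 else a2
        expl_h[heavy] <- expl_h[heavy] + 1L
        h_coord <- rbind(h_coord, c(heavy, coords[h, 1:3]))
      }
    }
    keep <- which(!is_h)
    remap <- match(seq_len(n), keep)
    bonds <- bonds[!is_h[bonds$a1] & !is_h[bonds$a2], , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    if (!is.null(h_coord)) h_coord[, 1] <- remap[h_coord[, 1]]
    element <- element[keep]; charge <- charge[keep]
    expl_h <- expl_h[keep]; coords <- coords[keep, , drop = FALSE]
    n <- length(element)
  }

  bondsum <- rep(0L, n)
  deg <- rep(0L, n)
  for (b in seq_len(nrow(bonds))) {
    bondsum[bonds$a1[b]] <- bondsum[bonds$a1[b]] + bonds$order[b]
    bondsum[bonds$a2[b]] <- bondsum[bonds$a2[b]] + bonds$order[b]
    deg[bonds$a1[b]] <- deg[bonds$a1[b]] + 1L
    deg[bonds$a2[b]] <- deg[bonds$a2[b]] + 1L
  }
  # explicit H bonds count toward the implied valence
  hcount <- pmax(0L, default_valence(element, charge) - bondsum - expl_h) + expl_h

  atoms <- tibble::tibble(
    idx = seq_len(n), element = element, charge = charge,
    hcount = as.integer(hcount), aromatic = FALSE, imid_n = FALSE,
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  bonds <- tibble::tibble(a1 = bonds$a1, a2 = bonds$a2,
                          order = bonds$order, aromatic = FALSE, in_ring = FALSE)

  mol <- structure(
    list(atoms = atoms, bonds = bonds, name = name, has_3d = has_3d,
         h_coords = h_coord, rings = list(), n_components = 1L),
    class = "cp_mol"
  )
  perceive_topology(mol)
}

default_valence <- function(element, charge) {
  base <- c(H = 0, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
            P = 3, S = 2, Cl = 1, Br = 1, I = 1)[element]
  v <- base + charge
  v[element == "C"] <- 4 - abs(charge[element == "C"])
  v[element == "B"] <- 3 - charge[element == "B"]
  pmax(0, v)
}

# ring perception, components, aromaticity, imidazolium normalisation
perceive_topology <- function(mol) {
  n <- nrow(mol$atoms)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = mol$bonds$a1, to = mol$bonds$a2),
    directed = FALSE, vertices = data.frame(name = seq_len(n))
  )
  mol$n_components <- igraph::components(g)$no

  if (nrow(mol$bonds) > 0) {
    br <- igraph::bridges(g)
    in_ring <- rep(TRUE, nrow(mol$bonds))
    in_ring[as.integer(br)] <- FALSE
    # vertices with no cycle through them: bonds already marked by bridges
    mol$bonds$in_ring <- in_ring
    mol$rings <- find_rings(mol, g)
  }
  mol <- perceive_aromaticity(mol)
  normalize_imidazolium(mol)
}

# smallest ring through every ring bond (an SSSR-like basis, adequate for
# the ring sizes this model distinguishes)
find_rings <- function(mol, g) {
  rings <- list()
  seen <- character(0)
  for (b in which(mol$bonds$in_ring)) {
    u <- mol$bonds$a1[b]; v <- mol$bonds$a2[b]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = u, to = v)$vpath[[1]])
    if (length(sp) == 0) next
    ring <- as.integer(igraph::as_ids(sp))
    key <- paste(sort(ring), collapse = "-")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1]] <- ring
    }
  }
  rings
}

bond_index <- function(mol, i, j) {
  which((mol$bonds$a1 == i & mol$bonds$a2 == j) |
          (mol$bonds$a1 == j & mol$bonds$a2 == i))
}

# Benzenoid aromaticity: a six-membered C/N ring is aromatic when each of its
# atoms either carries an endocyclic double bond (within that ring) or is
# already aromatic through a fused ring; iterate to a fixed point so that the
# middle rings of fused polycyclics are caught.  Five-membered heteroaromatics
# drawn with a saturated heteroatom (pyrrole, furan, thiophene) deliberately
# stay kekulized: the group notation types their carbons as sp2.
perceive_aromaticity <- function(mol) {
  repeat {
    changed <- FALSE
    for (ring in mol$rings) {
      if (length(ring) != 6) next
      if (!all(mol$atoms$element[ring] %in% c("C", "N"))) next
      ok <- vapply(ring, function(i) {
        if (mol$atoms$aromatic[i]) return(TRUE)
        for (j in setdiff(ring, i)) {
          bi <- bond_index(mol, i, j)
          if (length(bi) == 1 && (mol$bonds$order[bi] == 2 || mol$bonds$aromatic[bi])) {
            return(TRUE)
          }
        }
        FALSE
      }, logical(1))
      if (all(ok) && !all(mol$atoms$aromatic[ring])) {
        mol$atoms$aromatic[ring] <- TRUE
        for (i in ring) for (j in ring) {
          if (i < j) {
            bi <- bond_index(mol, i, j)
            if (length(bi) == 1) mol$bonds$aromatic[bi] <- TRUE
          }
        }
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  mol
}

# 1,3-dialkylimidazolium convention: the tables place the formal positive
# charge on the C2 carbon ("C(+) aromatic" / "H:N2") with both ring nitrogens
# neutral ("N aromatic" / "C2:C(+)") and the C4/C5 carbons typed
# "C aromatic" / "H:C:N".  The printed strings are direction-dependent: a ring
# nitrogen writes its bond to C4/C5 as single while C4/C5 write the same bond
# as aromatic, which is why the nitrogens are tagged (`imid_n`) rather than
# the bonds re-ordered.  SMILES conventionally charge a ring nitrogen, so
# matching rings are rewritten here.
normalize_imidazolium <- function(mol) {
  for (ring in mol$rings) {
    if (length(ring) != 5) next
    el <- mol$atoms$element[ring]
    if (sum(el == "N") != 2 || sum(el == "C") != 3) next
    ns <- ring[el == "N"]
    c2 <- intersect(
      intersect(neighbours_of(mol, ns[1]), neighbours_of(mol, ns[2])),
      ring
    )
    if (length(c2) != 1) next
    chg <- mol$atoms$charge[ring]
    if (sum(chg) != 1) next
    pos <- ring[chg == 1]
    if (!pos %in% c(ns, c2)) next
    # move the charge to C2, neutralise the nitrogens, aromatise the ring
    mol$atoms$charge[ns] <- 0L
    mol$atoms$charge[c2] <- 1L
    mol$atoms$aromatic[ring] <- TRUE
    mol$atoms$imid_n[ns] <- TRUE
    for (i in ring) for (j in ring) {
      if (i < j) {
        bi <- bond_index(mol, i, j)
        if (length(bi) == 1) {
          mol$bonds$aromatic[bi] <- TRUE
          mol$bonds$order[bi] <- 1L
        }
      }
    }
  }
  mol
}

neighbours_of <- function(mol, i) {
  c(mol$bonds$a2[mol$bonds$a1 == i], mol$bonds$a1[mol$bonds$a2 == i])
}

#' @export
print.cp_mol <- function(x, ...) {
  cat("<cp_mol> ", x$name, ": ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds, ", x$n_components, " component(s)",
      if (x$has_3d) ", 3D" else "", "\n", sep = "")
  invisible(x)
}

#' Write molecules to an SDF (V2000) file
#'
#' A minimal pass-through writer used for fixtures and round-trip checks:
#' element, coordinates, bond orders and formal charges (as `M  CHG` lines)
#' are preserved; folded-in hydrogens are not re-expanded.
#'
#' @param mols a `cp_mol` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "cp_mol")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    a <- mol$atoms; b <- mol$bonds
    writeLines(c(mol$name, "  cpgroups", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)), con)
    for (i in seq_len(nrow(a))) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         a$x[i], a$y[i], a$z[i], a$element[i]), con)
    }
    for (i in seq_len(nrow(b))) {
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", b$a1[i], b$a2[i], b$order[i]), con)
    }
    chg <- which(a$charge != 0)
    if (length(chg) > 0) {
      for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
        writeLines(paste0("M  CHG", sprintf("%3d", length(grp)),
                          paste0(sprintf("%4d%4d", grp, a$charge[grp]), collapse = "")),
                   con)
      }
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
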