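# Atom-group perception -----------------------------------------------------
#
# Every backbone atom (an atom with at least two immediate neighbours,
# hydrogens included) is described by two strings: an atom type (element,
# hybridization/aromaticity, formal charge) and an encoded neighbourhood.
# Terminal atoms -- halogens, carbonyl oxygens, nitrile nitrogens, hydrogens --
# never receive a group of their own; they only appear inside neighbour
# strings.  The notation must literally reproduce the published contribution
# tables, so the encoding rules below (element precedence, bond markers,
# charge suffixes, pi annotations) are fixed.

# element precedence inside neighbour strings; iodine is rendered "J"
NEIGHBOUR_ELEMENT_ORDER <- c("B", "C", "N", "O", "Si", "P", "S",
                             "F", "Cl", "Br", "J")
BOND_MARKER_ORDER <- c("", ":", "=", "#")

SPECIAL_KEYS <- c("EndocyclicBonds", "Angle60", "Angle90", "Angle102",
                  "COHn", "HHAcceptor")

atom_degree <- function(mol) {
  deg <- mol$atoms$hcount
  for (b in seq_len(nrow(mol$bonds))) {
    deg[mol$bonds$a1[b]] <- deg[mol$bonds$a1[b]] + 1L
    deg[mol$bonds$a2[b]] <- deg[mol$bonds$a2[b]] + 1L
  }
  deg
}

is_backbone <- function(mol) atom_degree(mol) >= 2L

# bonds incident to atom i, as a data frame with the partner atom
incident_bonds <- function(mol, i) {
  sel <- mol$bonds$a1 == i | mol$bonds$a2 == i
  b <- mol$bonds[sel, , drop = FALSE]
  b$partner <- ifelse(b$a1 == i, b$a2, b$a1)
  b
}

# An atom counts as unsaturated for the (pi) annotation when it is aromatic
# or is a C or N carrying a double or triple bond.  Hypervalent S and P
# (sulfonyl, phosphoryl) are not pi systems in this notation: the ester
# oxygen of an alkylsulfate is plain "CS", not "CS(pi)".
unsaturated_atoms <- function(mol) {
  uns <- mol$atoms$aromatic
  mult <- mol$bonds$order >= 2
  uns[mol$bonds$a1[mult]] <- TRUE
  uns[mol$bonds$a2[mult]] <- TRUE
  uns & mol$atoms$element %in% c("C", "N")
}

charge_suffix <- function(q) {
  if (q > 0) "(+)" else if (q < 0) "(-)" else ""
}

atom_type_of <- function(mol, i) {
  a <- mol$atoms[i, ]
  el <- a$element
  q <- a$charge
  ib <- incident_bonds(mol, i)
  nd <- sum(ib$order == 2 & !ib$aromatic)
  nt <- sum(ib$order == 3)
  bondsum <- sum(ib$order) + a$hcount
  chg <- charge_suffix(q)
  if (el == "C" || el == "N") {
    if (el == "N" && q < 0) return("N(-)")
    hyb <- if (a$aromatic) "aromatic"
           else if (nt >= 1 || nd >= 2) "sp"
           else if (nd == 1) "sp2"
           else "sp3"
    return(paste0(el, chg, " ", hyb))
  }
  if (el == "O") {
    if (q != 0 || a$aromatic) {
      stop("unsupported atom environment at atom ", i,
           " (charged or aromatic backbone oxygen)", call. = FALSE)
    }
    return("O")
  }
  if (el == "S") {
    if (q != 0) return(paste0("S", chg))
    return(if (bondsum <= 2) "S2" else "S4")
  }
  if (el == "P") {
    if (q != 0) return(paste0("P", chg))
    return(if (bondsum <= 3) "P3" else "P4")
  }
  if (el == "B") return(if (q < 0) "B(-)" else "B")
  if (el == "Si") return("Si")
  stop("unsupported atom environment at atom ", i, " (", el, ")", call. = FALSE)
}

neighbour_string_of <- function(mol, i, uns = unsaturated_atoms(mol)) {
  a <- mol$atoms[i, ]
  ib <- incident_bonds(mol, i)
  if (nrow(ib) > 0) {
    el <- mol$atoms$element[ib$partner]
    el[el == "I"] <- "J"
    marker <- ifelse(ib$aromatic, ":",
                     ifelse(ib$order == 2, "=", ifelse(ib$order == 3, "#", "")))
    # an imidazolium ring nitrogen writes its bonds to the uncharged ring
    # carbons as single (only the bond to C2(+) keeps the aromatic marker)
    if (mol$atoms$imid_n[i]) {
      marker[el == "C" & mol$atoms$charge[ib$partner] == 0] <- ""
    }
    ord <- order(match(el, NEIGHBOUR_ELEMENT_ORDER),
                 match(marker, BOND_MARKER_ORDER))
    el <- el[ord]; marker <- marker[ord]
    partner <- ib$partner[ord]
    run <- cumsum(c(TRUE, el[-1] != el[-length(el)] |
                      marker[-1] != marker[-length(marker)]))
    toks <- vapply(split(seq_along(run), run), function(idx) {
      paste0(marker[idx[1]], el[idx[1]],
             if (length(idx) > 1) length(idx) else "")
    }, character(1))
    body <- paste0(toks, collapse = "")
    qn <- mol$atoms$charge[partner]
  } else {
    body <- ""
    qn <- integer(0)
  }
  h <- if (a$hcount > 0) paste0("H", if (a$hcount > 1) a$hcount else "") else ""
  suffix <- paste0(if (any(qn > 0)) "(+)" else "", if (any(qn < 0)) "(-)" else "")
  atype <- atom_type_of(mol, i)
  pi_part <- ""
  if (atype %in% c("N sp3", "O", "S2") && nrow(ib) > 0) {
    npi <- sum(uns[ib$partner])
    if (npi > 0) pi_part <- paste0("(", if (npi > 1) npi else "", "pi)")
  }
  paste0(h, body, suffix, pi_part)
}

#' Assign atom groups to every backbone atom
#'
#' @param mol a `cp_mol`.
#' @return A tibble with one row per backbone atom: `atom` (index),
#'   `atom_type`, `neighbours` and the combined `key` used to look up
#'   contributions.
#' @examples
#' assign_atom_groups(parse_smiles("CCO"))
#' @export
assign_atom_groups <- function(mol) {
  stopifnot(inherits(mol, "cp_mol"))
  bb <- which(is_backbone(mol))
  uns <- unsaturated_atoms(mol)
  if (length(bb) == 0) {
    return(tibble::tibble(atom = integer(0), atom_type = character(0),
                          neighbours = character(0), key = character(0)))
  }
  atom_type <- vapply(bb, function(i) atom_type_of(mol, i), character(1))
  neighbours <- vapply(bb, function(i) neighbour_string_of(mol, i, uns), character(1))
  tibble::tibble(atom = bb, atom_type = atom_type, neighbours = neighbours,
                 key = paste(atom_type, neighbours, sep = "|"))
}

#' Refine hydroxy oxygens into O(prim)/O(sec)/O(tert)
#'
#' A hydroxy oxygen on a saturated carbon is re-typed according to the number
#' of carbon atoms attached to its carbinol carbon (the classical primary /
#' secondary / tertiary alcohol classes); the neighbourhood string of the
#' refined types is fixed at `"HC"`.  Hydroxy groups on unsaturated carbon
#' (phenols, carboxylic acids) keep the plain type `"O"` with neighbourhood
#' `"HC(pi)"`.  The refinement never changes the number of groups.
#'
#' @param groups result of [assign_atom_groups()].
#' @param mol the molecule the groups came from.
#' @param refined_types the refined type labels present in the parameter table
#'   (the refinement is skipped for tables that do not carry them).
#' @return The updated group tibble.
#' @export
refine_hydroxy_groups <- function(groups, mol,
                                  refined_types = c("O(prim)", "O(sec)", "O(tert)")) {
  if (length(refined_types) == 0) return(groups)
  uns <- unsaturated_atoms(mol)
  for (r in seq_len(nrow(groups))) {
    i <- groups$atom[r]
    a <- mol$atoms[i, ]
    if (a$element != "O" || a$hcount < 1) next
    ib <- incident_bonds(mol, i)
    if (nrow(ib) != 1) next
    cnb <- ib$partner[1]
    if (mol$atoms$element[cnb] != "C" || uns[cnb]) next
    ncarbon <- sum(mol$atoms$element[incident_bonds(mol, cnb)$partner] == "C")
    new_type <- if (ncarbon >= 3) "O(tert)" else if (ncarbon == 2) "O(sec)" else "O(prim)"
    if (!new_type %in% refined_types) next
    groups$atom_type[r] <- new_type
    groups$neighbours[r] <- "HC"
    groups$key[r] <- paste(new_type, "HC", sep = "|")
  }
  groups
}

#' Count the special groups of a molecule
#'
#' Special groups carry corrections that are not attached to a single backbone
#' atom: the number of endocyclic single bonds (non-aromatic ring bonds, each
#' fused-ring shared bond counted once), small-ring angle strain counters,
#' the polyol correction `(COH)n`, and intramolecular hydrogen bridges.
#'
#' Ring-angle counters need 3D coordinates: every pair of ring bonds meeting
#' at an atom defines a ring-internal angle, binned at <62 deg (Angle60),
#' 62-90 deg (Angle90) and 90-102 deg (Angle102).  Without coordinates a
#' topological fallback is used: each three-membered ring contributes three
#' Angle60 counts and each four-membered ring four Angle90 counts (those
#' angles are forced by topology); Angle102 stays zero.  Hydrogen bridges
#' (acidic H on O/N/S within 2.5 A of an O/N/F acceptor at least three bonds
#' away) are counted only when explicit-hydrogen 3D coordinates exist.
#'
#' @param mol a `cp_mol`.
#' @param cohn_mode counting convention for the polyol special: the default
#'   `"n_minus_one"` counts one occurrence per hydroxy group beyond the first,
#'   `"once"` flags any polyol with a single count, `"per_oh"` counts every
#'   hydroxy group of a polyol.
#' @return A named integer vector over the six special-group keys.
#' @examples
#' count_special_groups(parse_smiles("C1CCCCC1"))["EndocyclicBonds"]
#' @export
count_special_groups <- function(mol, cohn_mode = c("n_minus_one", "once", "per_oh")) {
  cohn_mode <- match.arg(cohn_mode)
  counts <- stats::setNames(integer(length(SPECIAL_KEYS)), SPECIAL_KEYS)

  counts["EndocyclicBonds"] <-
    sum(mol$bonds$in_ring & mol$bonds$order == 1 & !mol$bonds$aromatic &
          !bond_in_conjugated_ring(mol))

  if (mol$has_3d) {
    ang <- ring_internal_angles(mol)
    counts["Angle60"] <- sum(ang < 62)
    counts["Angle90"] <- sum(ang >= 62 & ang < 90)
    counts["Angle102"] <- sum(ang >= 90 & ang <= 102)
  } else {
    sizes <- lengths(mol$rings)
    counts["Angle60"] <- 3L * sum(sizes == 3)
    counts["Angle90"] <- 4L * sum(sizes == 4)
  }

  n_oh <- 0L
  for (i in seq_len(nrow(mol$atoms))) {
    a <- mol$atoms[i, ]
    if (a$element == "O" && a$hcount >= 1) {
      nb <- incident_bonds(mol, i)$partner
      if (any(mol$atoms$element[nb] == "C")) n_oh <- n_oh + 1L
    }
  }
  counts["COHn"] <- switch(cohn_mode,
    n_minus_one = max(0L, n_oh - 1L),
    once = as.integer(n_oh > 1L),
    per_oh = if (n_oh > 1L) n_oh else 0L)

  counts["HHAcceptor"] <- count_h_bridges(mol)
  counts
}

# The endocyclic-bond special corrects for the rotational freedom a ring
# removes from a saturated framework, so bonds inside pi-conjugated rings do
# not count even when the ring is drawn kekulized (the five-membered ring of
# an indole contributes nothing, exactly like a benzenoid ring).  A ring is
# conjugated when every member is aromatic, multiply bonded, or a lone-pair
# heteroatom (N, O, S).
bond_in_conjugated_ring <- function(mol) {
  uns <- mol$atoms$aromatic
  mult <- mol$bonds$order >= 2
  uns[mol$bonds$a1[mult]] <- TRUE
  uns[mol$bonds$a2[mult]] <- TRUE
  excl <- rep(FALSE, nrow(mol$bonds))
  for (ring in mol$rings) {
    if (all(uns[ring] | mol$atoms$element[ring] %in% c("N", "O", "S"))) {
      for (i in ring) for (j in ring) {
        if (i < j) {
          bi <- bond_index(mol, i, j)
          if (length(bi) == 1) excl[bi] <- TRUE
        }
      }
    }
  }
  excl
}

# all ring-internal bond angles (degrees): every pair of ring bonds at an atom
ring_internal_angles <- function(mol) {
  out <- numeric(0)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  for (i in seq_len(nrow(mol$atoms))) {
    ib <- incident_bonds(mol, i)
    ring_nb <- ib$partner[ib$in_ring]
    if (length(ring_nb) < 2) next
    prs <- utils::combn(ring_nb, 2)
    for (k in seq_len(ncol(prs))) {
      v1 <- xyz[prs[1, k], ] - xyz[i, ]
      v2 <- xyz[prs[2, k], ] - xyz[i, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      out <- c(out, acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
    }
  }
  out
}

count_h_bridges <- function(mol, dmax = 2.5, min_sep = 3L) {
  if (!mol$has_3d || is.null(mol$h_coords)) return(0L)
  donors <- which(mol$atoms$element %in% c("O", "N", "S"))
  acceptors <- which(mol$atoms$element %in% c("O", "N", "F"))
  if (length(donors) == 0 || length(acceptors) == 0) return(0L)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = mol$bonds$a1, to = mol$bonds$a2),
    directed = FALSE, vertices = data.frame(name = seq_len(nrow(mol$atoms))))
  dist <- igraph::distances(g)
  n <- 0L
  hc <- mol$h_coords
  for (r in seq_len(nrow(hc))) {
    parent <- hc[r, 1]
    if (!parent %in% donors) next
    for (acc in acceptors) {
      if (acc == parent) next
      if (is.finite(dist[parent, acc]) && dist[parent, acc] < min_sep) next
      d <- sqrt(sum((hc[r, 2:4] - unlist(mol$atoms[acc, c("x", "y", "z")]))^2))
      if (d < dmax) n <- n + 1L
    }
  }
  n
}

#' Perceive the full group-count vector of a molecule
#'
#' Combines [assign_atom_groups()], [refine_hydroxy_groups()] and
#' [count_special_groups()] into the count vector of the additivity model:
#' the occurrence count A_i of every atom group plus the count B_j of every
#' special group.
#'
#' @inheritParams count_special_groups
#' @param refine whether to apply the hydroxy refinement (it is switched off
#'   automatically for tables without the refined oxygen types).
#' @return A tibble with columns `key`, `kind` (`"atom"` or `"special"`) and
#'   `count`; the per-atom assignment is attached as attribute `"groups"`.
#' @examples
#' perceive_groups(parse_smiles("OCC1CCCCC1"))
#' @export
perceive_groups <- function(mol, cohn_mode = "n_minus_one", refine = TRUE) {
  groups <- assign_atom_groups(mol)
  if (refine) groups <- refine_hydroxy_groups(groups, mol)
  tab <- table(groups$key)
  specials <- count_special_groups(mol, cohn_mode = cohn_mode)
  specials <- specials[specials > 0]
  out <- tibble::tibble(
    key = c(names(tab), names(specials)),
    kind = c(rep("atom", length(tab)), rep("special", length(specials))),
    count = c(as.integer(tab), as.integer(specials))
  )
  attr(out, "groups") <- groups
  out
}

#' Per-atom perception dump for auditing
#'
#' @param mol a `cp_mol`.
#' @param table optional contribution table; when given, the matching entry
#'   number is attached per atom.
#' @return A tibble (atom index, element, atom type, neighbour string, key,
#'   entry number if a table was supplied).
#' @export
perception_report <- function(mol, table = NULL) {
  g <- refine_hydroxy_groups(assign_atom_groups(mol), mol)
  out <- tibble::tibble(atom = g$atom,
                        element = mol$atoms$element[g$atom],
                        atom_type = g$atom_type, neighbours = g$neighbours,
                        key = g$key)
  if (!is.null(table)) out$entry <- table$entry[match(out$key, table$key)]
  out
}
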