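# PDB input, atom selection and shift-table output.
#
# The reader implements the subset of wwPDB v3.3 this predictor needs
# (ATOM/HETATM/MODEL/ENDMDL/TER), with the policies a single-conformer
# predictor wants: first MODEL only, highest-occupancy alternate location,
# insertion codes kept as part of residue identity.  Writing goes through
# bio3d, which also serves as an independent parser in the test suite.

#' Read a protein structure from a PDB file
#'
#' @param source Path to a PDB file, or a character vector of PDB lines.
#' @return Object of class `protein_structure`: list with `atoms` (one row
#'   per accepted ATOM/HETATM record, file order preserved), `residues`
#'   (runs of (chain, res_seq, insertion code)), and `n_atoms`.
#' @details Only the first MODEL of a multi-model file is read.  When a
#'   residue carries alternate locations, the highest-occupancy alternate is
#'   kept (ties broken by file order).  HETATM records are retained in the
#'   atom list but non-standard residues are ignored by [get_select()].
#' @export
read_pdb <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  lineno <- seq_along(lines)
  rec <- substr(lines, 1, 6)

  # restrict to the first model if MODEL records are present
  m_start <- which(rec == "MODEL ")
  if (length(m_start) > 0) {
    m_end <- which(rec == "ENDMDL")
    last <- if (length(m_end) > 0) m_end[1] else length(lines)
    keep_window <- seq(m_start[1], last)
    in_model <- lineno %in% keep_window
  } else {
    in_model <- rep(TRUE, length(lines))
  }

  is_atom <- (rec == "ATOM  " | rec == "HETATM") & in_model
  if (!any(is_atom))
    stop("empty structure: no ATOM/HETATM records found", call. = FALSE)
  al <- lines[is_atom]
  ano <- lineno[is_atom]

  num_field <- function(txt, what, ln) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v) & trimws(txt) != "")
    miss <- which(trimws(txt) == "")
    bad <- sort(c(bad, if (what %in% c("x", "y", "z")) miss))
    if (length(bad) > 0)
      stop(sprintf("PDB format error: unparseable %s coordinate field at line %d",
                   what, ln[bad[1]]), call. = FALSE)
    v
  }

  x <- num_field(substr(al, 31, 38), "x", ano)
  y <- num_field(substr(al, 39, 46), "y", ano)
  z <- num_field(substr(al, 47, 54), "z", ano)
  occ <- suppressWarnings(as.numeric(substr(al, 55, 60)))
  occ[is.na(occ)] <- 1.0
  serial <- suppressWarnings(as.integer(substr(al, 7, 11)))
  serial[is.na(serial)] <- seq_len(sum(is_atom))[is.na(serial)]
  name <- trimws(substr(al, 13, 16))
  alt <- substr(al, 17, 17)
  res_name <- trimws(substr(al, 18, 20))
  chain <- substr(al, 22, 22)
  res_seq <- suppressWarnings(as.integer(substr(al, 23, 26)))
  if (anyNA(res_seq))
    stop(sprintf("PDB format error: unparseable residue number at line %d",
                 ano[which(is.na(res_seq))[1]]), call. = FALSE)
  icode <- substr(al, 27, 27)
  elesy <- trimws(substr(al, 77, 78))
  derived <- toupper(substr(gsub("[0-9' ]", "", name), 1, 1))
  element <- ifelse(elesy == "", derived, elesy)

  atoms <- data.frame(
    serial = serial, name = name, element = element,
    res_name = res_name, res_seq = res_seq, chain_id = chain,
    insert = icode, x = x, y = y, z = z,
    occupancy = occ, alt_loc = alt,
    het = rec[is_atom] == "HETATM",
    stringsAsFactors = FALSE)

  # alternate locations: keep the highest-occupancy alternate per atom site
  has_alt <- atoms$alt_loc != " " & atoms$alt_loc != ""
  if (any(has_alt)) {
    site <- paste(atoms$chain_id, atoms$res_seq, atoms$insert, atoms$name,
                  sep = "|")
    keep <- rep(TRUE, nrow(atoms))
    for (s in unique(site[has_alt])) {
      idx <- which(site == s)
      if (length(idx) > 1L) {
        best <- idx[which.max(atoms$occupancy[idx])]  # ties: first in file
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL
  }

  new_protein_structure(atoms)
}

# Assemble the residue table and cache environment around an atom table.
new_protein_structure <- function(atoms) {
  rid <- paste(atoms$chain_id, atoms$res_seq, atoms$insert, sep = "|")
  runs <- rle(rid)
  last <- cumsum(runs$lengths)
  first <- c(1L, head(last, -1L) + 1L)
  residues <- data.frame(
    chain_id = atoms$chain_id[first],
    res_seq = atoms$res_seq[first],
    insert = atoms$insert[first],
    res_name = atoms$res_name[first],
    first = first, last = last,
    stringsAsFactors = FALSE)
  # ordinal position of each residue within its chain (insertion-code safe)
  residues$chain_ord <- stats::ave(seq_len(nrow(residues)),
                                   residues$chain_id, FUN = seq_along)
  atoms$res_index <- rep(seq_len(nrow(residues)), runs$lengths)

  structure(
    list(atoms = atoms, residues = residues, n_atoms = nrow(atoms),
         cache = new.env(parent = emptyenv())),
    class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %d atoms, %d residues, %d chain(s)\n",
              x$n_atoms, nrow(x$residues), length(unique(x$residues$chain_id))))
  invisible(x)
}

#' Write a structure to a PDB file
#'
#' @param structure A `protein_structure`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(structure, file) {
  a <- structure$atoms
  chain <- a$chain_id
  chain[nchar(chain) != 1L] <- substr(chain[nchar(chain) != 1L], 1, 1)
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$res_seq, resid = a$res_name,
    eleno = a$serial, elety = a$name,
    chain = chain, insert = ifelse(a$insert == " ", "", a$insert),
    o = a$occupancy, b = rep(0, nrow(a)), elesy = a$element,
    end = TRUE)
  invisible(file)
}

# ---- selection -------------------------------------------------------------

# Atom-name lookup within one residue; returns NA when the atom is absent.
find_atom <- function(names_norm, range, target) {
  hit <- range[names_norm[range] == target]
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Build (and cache) the atom selection of a structure
#'
#' Collects everything the descriptors need: the six query-nucleus index
#' lists (CA, CB, C', HN, N, HA), backbone H-bond donors (N, HN) and
#' acceptors (O, C'), backbone amide O-C'-N triples, the side-chain
#' anisotropy groups of Asn/Gln (OCN), Asp/Glu (OCO) and Arg (NCN), and the
#' aromatic rings of Phe, Tyr, His and Trp (Trp contributes both its
#' five- and six-membered ring).
#'
#' The selection is computed once per structure and memoized on the
#' structure's cache environment; repeated calls return the identical cached
#' object.  `select_eval_count()` exposes the evaluation counter.
#'
#' @param structure A `protein_structure`.
#' @return Object of class `selection_set`.
#' @export
get_select <- function(structure) {
  cache <- structure$cache
  if (!is.null(cache$selection)) return(cache$selection)
  cache$select_evals <- (if (is.null(cache$select_evals)) 0L
                         else cache$select_evals) + 1L

  atoms <- structure$atoms
  res <- structure$residues
  nn <- atoms$name
  is_h <- atoms$element == "H"
  nn[is_h] <- normalize_h_name(nn[is_h])

  std <- which(res$res_name %in% STANDARD_AA)
  n_res <- nrow(res)
  q <- list(CA = integer(), CB = integer(), C = integer(),
            HN = integer(), N = integer(), HA = integer())
  qres <- list(CA = integer(), CB = integer(), C = integer(),
               HN = integer(), N = integer(), HA = integer())
  donors <- NULL; acceptors <- NULL; amide <- NULL
  side <- list(); rings <- list()

  atom_of <- matrix(NA_integer_, nrow = n_res, ncol = 6,
                    dimnames = list(NULL, c("N", "CA", "C", "O", "HN", "HA")))
  for (i in std) {
    rng <- seq.int(res$first[i], res$last[i])
    rname <- res$res_name[i]
    ha_name <- if (rname == "GLY") "HA2" else "HA"
    atom_of[i, "N"] <- find_atom(nn, rng, "N")
    atom_of[i, "CA"] <- find_atom(nn, rng, "CA")
    atom_of[i, "C"] <- find_atom(nn, rng, "C")
    atom_of[i, "O"] <- find_atom(nn, rng, "O")
    atom_of[i, "HN"] <- find_atom(nn, rng, "HN")
    atom_of[i, "HA"] <- find_atom(nn, rng, ha_name)
    cb <- find_atom(nn, rng, "CB")

    add <- function(class, idx) {
      if (!is.na(idx)) {
        q[[class]] <<- c(q[[class]], idx)
        qres[[class]] <<- c(qres[[class]], i)
      }
    }
    add("CA", atom_of[i, "CA"]); add("CB", cb); add("C", atom_of[i, "C"])
    add("N", atom_of[i, "N"]); add("HN", atom_of[i, "HN"])
    add("HA", atom_of[i, "HA"])

    if (rname != "PRO" && !is.na(atom_of[i, "N"]) && !is.na(atom_of[i, "HN"]))
      donors <- rbind(donors, c(atom_of[i, "N"], atom_of[i, "HN"], i))
    if (!is.na(atom_of[i, "O"]) && !is.na(atom_of[i, "C"]))
      acceptors <- rbind(acceptors, c(atom_of[i, "O"], atom_of[i, "C"], i))

    sc <- SIDECHAIN_ANI[[rname]]
    if (!is.null(sc)) {
      idx <- vapply(sc$atoms, function(a) find_atom(nn, rng, a), integer(1))
      if (!anyNA(idx))
        side[[length(side) + 1L]] <- list(idx = unname(idx), kind = sc$kind,
                                          res_index = i)
    }
    for (rk in names(RING_DEFS)) {
      rd <- RING_DEFS[[rk]]
      if (rd$res != rname) next
      idx <- vapply(rd$atoms, function(a) find_atom(nn, rng, a), integer(1))
      if (anyNA(idx)) {
        warning(sprintf("residue %s %s%d%s: incomplete %s ring, omitted",
                        rname, res$chain_id[i], res$res_seq[i],
                        trimws(res$insert[i]), rk), call. = FALSE)
      } else {
        rings[[length(rings) + 1L]] <- list(kind = rk, idx = unname(idx),
                                            res_index = i)
      }
    }
  }

  # backbone amide groups: O(i), C'(i), N(i+1) for peptide-bonded neighbours
  for (i in std) {
    j <- i + 1L
    if (j > n_res || res$chain_id[j] != res$chain_id[i]) next
    if (!(res$res_name[j] %in% STANDARD_AA)) next
    if (!anyNA(atom_of[i, c("O", "C")]) && !is.na(atom_of[j, "N"]))
      amide <- rbind(amide, c(atom_of[i, "O"], atom_of[i, "C"],
                              atom_of[j, "N"], i, j))
  }

  to_mat <- function(m, nms) {
    if (is.null(m)) m <- matrix(integer(), 0, length(nms))
    colnames(m) <- nms
    m
  }
  sel <- structure(
    list(query_nuclei = q, query_res = qres,
         donors = to_mat(donors, c("n", "h", "res")),
         acceptors = to_mat(acceptors, c("o", "c", "res")),
         amide_groups = to_mat(amide, c("o", "c", "n", "res", "res_next")),
         sidechain_groups = side,
         rings = rings,
         backbone = atom_of,
         proton_filtered = FALSE),
    class = "selection_set")
  cache$selection <- sel
  sel
}

#' Number of times the selection of a structure has been computed
#'
#' @param structure A `protein_structure`.
#' @return Integer count (0 if [get_select()] was never called).
#' @export
select_eval_count <- function(structure) {
  n <- structure$cache$select_evals
  if (is.null(n)) 0L else n
}

#' @export
print.selection_set <- function(x, ...) {
  cat(sprintf(paste0("<selection_set> queries: %s; %d donors, %d acceptors, ",
                     "%d amide groups, %d side-chain groups, %d rings\n"),
              paste(sprintf("%s=%d", names(x$query_nuclei),
                            lengths(x$query_nuclei)), collapse = " "),
              nrow(x$donors), nrow(x$acceptors), nrow(x$amide_groups),
              length(x$sidechain_groups), length(x$rings)))
  invisible(x)
}

#' Drop query protons the prediction model cannot use
#'
#' Removes amide protons whose residue lacks a backbone N, alpha protons
#' whose residue lacks a CA, and any query proton sitting in a residue with
#' an incomplete backbone (missing any of N, CA, C').  Heavy-atom query
#' lists are untouched.  The filter is idempotent and runs in time linear in
#' the number of query protons.
#'
#' @param selection A `selection_set` built from `structure`.
#' @param structure The `protein_structure` the selection came from.
#' @return A filtered `selection_set` with `proton_filtered = TRUE`.
#' @export
clear_protons <- function(selection, structure) {
  bb <- selection$backbone
  complete <- !is.na(bb[, "N"]) & !is.na(bb[, "CA"]) & !is.na(bb[, "C"])
  keep_class <- function(class, anchor) {
    r <- selection$query_res[[class]]
    ok <- complete[r] & !is.na(bb[r, anchor])
    selection$query_nuclei[[class]] <<- selection$query_nuclei[[class]][ok]
    selection$query_res[[class]] <<- r[ok]
  }
  keep_class("HN", "N")
  keep_class("HA", "CA")
  selection$proton_filtered <- TRUE
  selection
}

# ---- shift tables ----------------------------------------------------------

#' Write a shift table
#'
#' Tab-separated with header `chain res_seq res_name nucleus shift_ppm`.
#'
#' @param table Data frame with those five columns (a `shift_table`).
#' @param file Output path.
#' @param digits Number of decimal places for `shift_ppm`; `NA` writes full
#'   precision.
#' @return `file`, invisibly.
#' @export
write_shift_table <- function(table, file, digits = NA) {
  out <- table[, c("chain", "res_seq", "res_name", "nucleus", "shift_ppm")]
  if (!is.na(digits)) out$shift_ppm <- sprintf(paste0("%.", digits, "f"),
                                               out$shift_ppm)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a shift table written by [write_shift_table()]
#'
#' @param file Path to a tab-separated shift table.
#' @return A `shift_table` data frame.
#' @export
read_shift_table <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "character",
                                         "character", "numeric"),
                          stringsAsFactors = FALSE)
  class(df) <- c("shift_table", "data.frame")
  df
}
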