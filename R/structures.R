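# Nucleic-acid structure container and PDB I/O.
#
# A structure is a list with an `atoms` data.frame (one row per heavy atom,
# file order preserved) and a free-text `label`.  Columns:
#   chain   chain identifier (single character)
#   resno   PDB residue number (verbatim, may be non-contiguous)
#   ins     insertion code ("" if none)
#   resname canonical residue name after alias mapping (A/C/G/U/DA/DC/DG/DT)
#   elety   PDB atom name, e.g. "C4'"
#   element element symbol
#   x, y, z coordinates in Angstrom
#   serial  atom serial number

# canonical nucleic alphabet plus common aliases / modified residues
.NA_ALPHABET <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT")

.NA_ALIASES <- c(
  A = "A", C = "C", G = "G", U = "U",
  DA = "DA", DC = "DC", DG = "DG", DT = "DT",
  RA = "A", RC = "C", RG = "G", RU = "U",
  ADE = "A", CYT = "C", GUA = "G", URA = "U", URI = "U", THY = "DT",
  T = "DT", DU = "U",
  PSU = "U", H2U = "U", "4SU" = "U", "5MU" = "U",
  "1MA" = "A", "5MC" = "C", OMC = "C", OMG = "G", "7MG" = "G",
  "2MG" = "G", M2G = "G", I = "G", YG = "G", "5BU" = "U"
)

.SOLVENT <- c("HOH", "WAT", "DOD", "MG", "NA", "K", "CL", "ZN", "MN",
              "CA", "SR", "CS", "BR", "IOD", "SO4", "PO4", "GOL", "EDO",
              "SPD", "SPM")

.new_structure <- function(atoms, label = "") {
  structure(list(atoms = atoms, label = label), class = "na_structure")
}

#' Read a nucleic-acid structure from PDB text
#'
#' Parses ATOM/HETATM records into a heavy-atom structure.  Hydrogens,
#' waters and ions are dropped; alternate locations other than `' '`/`'A'`
#' are dropped; only the first MODEL of an ensemble is kept.  Modified
#' nucleotides are mapped onto the standard alphabet through a small alias
#' table; residue names outside it raise an error naming the residue.
#'
#' @param file path to a PDB file, or a character vector of PDB lines via
#'   `text`.
#' @param text PDB text given directly (overrides `file`).
#' @param chains optional character vector of chain identifiers to keep.
#' @param label free-text label stored with the structure.
#' @return An object of class `na_structure`.
#' @export
read_structure <- function(file = NULL, text = NULL, chains = NULL, label = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    text <- readLines(file, warn = FALSE)
    if (is.null(label)) label <- basename(file)
  }
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (is.null(label)) label <- ""

  # first MODEL only
  mstart <- grep("^MODEL", text)
  if (length(mstart) > 1L) {
    mend <- grep("^ENDMDL", text)
    if (length(mend) >= 1L) text <- text[seq_len(mend[1] - 1L)]
  }
  rec <- substr(text, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- text[keep]
  if (length(lines) == 0L) stop("no ATOM records found in PDB input")
  is_het <- rec[keep] == "HETATM"

  fld <- function(a, b) trimws(substr(lines, a, b))
  serial <- suppressWarnings(as.integer(fld(7, 11)))
  elety <- fld(13, 16)
  altloc <- substr(lines, 17, 17)
  resname_raw <- fld(18, 20)
  chain <- substr(lines, 22, 22)
  resno <- suppressWarnings(as.integer(fld(23, 26)))
  ins <- trimws(substr(lines, 27, 27))
  x <- as.numeric(fld(31, 38))
  y <- as.numeric(fld(39, 46))
  z <- as.numeric(fld(47, 54))
  element <- toupper(fld(77, 78))

  # element fallback from the atom name (first alphabetic character)
  noelem <- element == ""
  if (any(noelem)) {
    guess <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9']*", "", elety[noelem])))
    element[noelem] <- substr(guess, 1, 1)
    two <- guess %in% c("BR", "CL", "FE", "MG", "MN", "ZN", "NA")
    element[noelem][two] <- guess[two]
  }

  ok <- altloc %in% c(" ", "A")
  solvent <- is_het & (resname_raw %in% .SOLVENT)
  hydrogen <- element %in% c("H", "D")
  ok <- ok & !solvent & !hydrogen
  serial <- serial[ok]; elety <- elety[ok]; resname_raw <- resname_raw[ok]
  chain <- chain[ok]; resno <- resno[ok]; ins <- ins[ok]
  x <- x[ok]; y <- y[ok]; z <- z[ok]; element <- element[ok]
  if (length(elety) == 0L) stop("no heavy atoms left after filtering")

  unknown <- !(resname_raw %in% names(.NA_ALIASES))
  if (any(unknown))
    stop("residue name(s) outside the nucleic-acid alphabet: ",
         paste(unique(resname_raw[unknown]), collapse = ", "))
  resname <- unname(.NA_ALIASES[resname_raw])

  if (!is.null(chains)) {
    missing <- setdiff(chains, unique(chain))
    if (length(missing) > 0L)
      stop("requested chain(s) not present: ", paste(missing, collapse = ", "))
    sel <- chain %in% chains
    serial <- serial[sel]; elety <- elety[sel]; resname <- resname[sel]
    chain <- chain[sel]; resno <- resno[sel]; ins <- ins[sel]
    x <- x[sel]; y <- y[sel]; z <- z[sel]; element <- element[sel]
  }
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z)))
    stop("non-finite coordinates in PDB input")

  atoms <- data.frame(chain = chain, resno = resno, ins = ins,
                      resname = resname, elety = elety, element = element,
                      x = x, y = y, z = z, serial = serial,
                      stringsAsFactors = FALSE)
  .new_structure(atoms, label)
}

#' @export
print.na_structure <- function(x, ...) {
  a <- x$atoms
  ch <- unique(a$chain)
  cat(sprintf("na_structure%s: %d chain(s) [%s], %d residues, %d heavy atoms\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(ch), paste(ch, collapse = ","),
              n_residues(x), nrow(a)))
  invisible(x)
}

# residue identity key: chain | resno | insertion code
.res_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")

#' Number of residues in a structure
#' @param s an `na_structure`.
#' @return integer count.
#' @export
n_residues <- function(s) length(unique(.res_key(s$atoms)))

#' Coordinate matrix of a structure
#' @param s an `na_structure`.
#' @return numeric matrix with one row per atom, columns x, y, z.
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

`coords<-` <- function(s, value) {
  s$atoms$x <- value[, 1]; s$atoms$y <- value[, 2]; s$atoms$z <- value[, 3]
  s
}

#' Select one named atom per residue
#'
#' Returns the coordinates of the atom called `atom_name` in each residue,
#' in residue order.  Residues lacking the atom are skipped and counted.
#'
#' @param s an `na_structure`.
#' @param atom_name PDB atom name, e.g. `"C4'"`.
#' @return A list with `keys` (residue keys `chain|resno|ins`), `coords`
#'   (matrix, one row per selected atom) and `skipped` (number of residues
#'   without the atom).
#' @export
select_atoms <- function(s, atom_name) {
  a <- s$atoms
  keys <- .res_key(a)
  res_order <- unique(keys)
  hit <- a$elety == atom_name
  hit_keys <- keys[hit]
  m <- match(res_order, hit_keys)      # first match per residue, residue order
  found <- !is.na(m)
  idx <- which(hit)[m[found]]
  list(keys = res_order[found],
       coords = cbind(x = a$x[idx], y = a$y[idx], z = a$z[idx]),
       skipped = sum(!found))
}

#' Rigid transform (proper rotation + translation)
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation matrix is not proper (det != +1)")
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' Compose two rigid transforms (apply `a` first, then `b`)
#' @param a,b `rigid_transform` objects sharing the same rotation center.
#' @return the composed `rigid_transform`.
#' @export
compose_transforms <- function(b, a) {
  # x -> Rb (Ra x + ta) + tb
  rigid_transform(b$R %*% a$R, as.numeric(b$R %*% a$t) + b$t)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$R), -as.numeric(t(t$R) %*% t$t))
}

#' Apply a rigid transform to a structure
#'
#' Maps every coordinate `x -> R (x - center) + center + t`; topology is
#' untouched.
#'
#' @param s an `na_structure`.
#' @param transform a `rigid_transform`.
#' @param center rotation center (default origin).
#' @return the transformed `na_structure`.
#' @export
apply_transform <- function(s, transform, center = c(0, 0, 0)) {
  if (!inherits(transform, "rigid_transform"))
    transform <- do.call(rigid_transform, transform)
  xyz <- coords(s)
  xyz <- sweep(xyz, 2, center) %*% t(transform$R)
  xyz <- sweep(xyz, 2, center + transform$t, "+")
  coords(s) <- xyz
  s
}

# fixed-width PDB ATOM records for one structure's atoms
.format_atom_lines <- function(atoms, serial_start = 1L) {
  n <- nrow(atoms)
  name4 <- ifelse(nchar(atoms$elety) >= 4, substr(atoms$elety, 1, 4),
                  sprintf(" %-3s", atoms$elety))
  sprintf("ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq(serial_start, length.out = n) %% 100000L,
          name4, atoms$resname, atoms$chain, atoms$resno,
          ifelse(nzchar(atoms$ins), atoms$ins, " "),
          atoms$x, atoms$y, atoms$z, 1, 0, atoms$element)
}

#' Write a structure to PDB text
#'
#' @param s an `na_structure`.
#' @param file optional output path; if `NULL` the lines are returned.
#' @param remarks optional character vector written as REMARK lines.
#' @return invisibly, the PDB lines.
#' @export
write_structure <- function(s, file = NULL, remarks = NULL) {
  lines <- character(0)
  if (!is.null(remarks)) lines <- c(lines, remarks)
  a <- s$atoms
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, , drop = FALSE]
    lines <- c(lines, .format_atom_lines(sub, serial_start = length(lines)), "TER")
  }
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

.CHAIN_POOL <- c(LETTERS, letters, 0:9)

#' Write a docked model (receptor + posed ligand) as PDB text
#'
#' Receptor chains come first; ligand chains are renamed if they collide
#' with receptor chain identifiers.  REMARK 3 lines carry the model rank and
#' both scores so they can be recovered by parsing the file.
#'
#' @param receptor,ligand_pose `na_structure` objects.
#' @param rank 1-based model rank (>= 1).
#' @param scores named list or vector with elements `shape` and `energy`.
#' @param file optional output path.
#' @return invisibly, the PDB lines.
#' @export
write_model <- function(receptor, ligand_pose, rank, scores, file = NULL) {
  stopifnot(rank >= 1)
  rec_ch <- unique(receptor$atoms$chain)
  lig <- ligand_pose
  lig_ch <- unique(lig$atoms$chain)
  clash <- intersect(lig_ch, rec_ch)
  if (length(clash) > 0L) {
    avail <- setdiff(.CHAIN_POOL, c(rec_ch, lig_ch))
    if (length(avail) < length(clash)) stop("chain identifiers exhausted")
    map <- stats::setNames(lig_ch, lig_ch)
    map[clash] <- avail[seq_along(clash)]
    lig$atoms$chain <- unname(map[lig$atoms$chain])
  }
  remarks <- c(sprintf("REMARK   3 RANK %d", as.integer(rank)),
               sprintf("REMARK   3 SHAPE_SCORE %.6f", as.numeric(scores[["shape"]])),
               sprintf("REMARK   3 ENERGY_SCORE %.6f", as.numeric(scores[["energy"]])))
  lines <- remarks
  for (ch in unique(receptor$atoms$chain)) {
    sub <- receptor$atoms[receptor$atoms$chain == ch, , drop = FALSE]
    lines <- c(lines, .format_atom_lines(sub, length(lines)), "TER")
  }
  for (ch in unique(lig$atoms$chain)) {
    sub <- lig$atoms[lig$atoms$chain == ch, , drop = FALSE]
    lines <- c(lines, .format_atom_lines(sub, length(lines)), "TER")
  }
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Recover rank and scores from a written model's REMARK lines
#' @param lines PDB lines (or a file path).
#' @return list with `rank`, `shape`, `energy`.
#' @export
read_model_scores <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  g <- function(tag) {
    ln <- grep(paste0("^REMARK   3 ", tag, " "), lines, value = TRUE)
    if (length(ln) == 0L) return(NA_real_)
    as.numeric(sub(paste0("^REMARK   3 ", tag, " "), "", ln[1]))
  }
  list(rank = as.integer(g("RANK")), shape = g("SHAPE_SCORE"),
       energy = g("ENERGY_SCORE"))
}

# merge two structures (receptor + ligand) into one, used by evaluation
.bind_structures <- function(a, b) {
  .new_structure(rbind(a$atoms, b$atoms), label = paste(a$label, b$label))
}
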