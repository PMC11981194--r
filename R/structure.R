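.water_names <- c("HOH", "WAT", "H2O", "DOD")

#' Read a structure file into an atom table
#'
#' Reads PDB or mmCIF (by file extension) via bio3d and returns a plain
#' atom table in author residue numbering. Alternate locations other than
#' 'A' or blank are dropped with a message.
#'
#' @param path Path to a `.pdb` / `.ent` or `.cif` file.
#' @return Data frame with columns `chain`, `resno`, `resid`, `atom`,
#'   `element`, `x`, `y`, `z` (angstroms).
#' @export
read_structure <- function(path) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  a <- pdb$atom
  alt <- a$alt
  keep_alt <- is.na(alt) | alt %in% c("", "A")
  if (!all(keep_alt)) {
    message("dropping ", sum(!keep_alt), " alternate-location atoms ",
            "(keeping altloc 'A' or blank)")
    a <- a[keep_alt, , drop = FALSE]
  }
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)))
    elem <- toupper(substr(trimws(a$elety), 1L, 1L))
  atoms <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                      atom = a$elety, element = toupper(trimws(elem)),
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  atoms
}

.filter_heavy <- function(atoms, include_waters = FALSE) {
  keep <- !(atoms$element %in% c("H", "D"))
  if (!include_waters) keep <- keep & !(atoms$resid %in% .water_names)
  atoms[keep, , drop = FALSE]
}

#' Inter-chain heavy-atom contacts
#'
#' Lists all heavy-atom pairs between two chains whose Euclidean distance
#' lies in `[dmin, dmax]` (default 2.5-3.6 angstroms, the polar-contact
#' window used to define the receptor-effector interface). Hydrogens are
#' always excluded; waters are excluded unless `include_waters = TRUE`.
#' Output order is deterministic: by chain-A residue number, then distance.
#'
#' @param atoms Atom table from [read_structure()] or [make_toy_complex()].
#' @param chain_a,chain_b Chain identifiers (must differ).
#' @param dmin,dmax Inclusive distance bounds, `0 < dmin < dmax`.
#' @param include_waters Keep water molecules.
#' @param method `"grid"` (cell-list accelerator, default) or `"brute"`
#'   (all-pairs); both give identical output.
#' @return Data frame of contact pairs: `resno_a`, `resid_a`, `atom_a`,
#'   `resno_b`, `resid_b`, `atom_b`, `distance`.
#' @export
find_contacts <- function(atoms, chain_a, chain_b, dmin = 2.5, dmax = 3.6,
                          include_waters = FALSE,
                          method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(dmin > 0, dmin < dmax)
  if (identical(chain_a, chain_b)) stop("chains must differ")
  atoms <- .filter_heavy(atoms, include_waters)
  A <- atoms[atoms$chain == chain_a, , drop = FALSE]
  B <- atoms[atoms$chain == chain_b, , drop = FALSE]
  if (!nrow(A)) stop("chain ", sQuote(chain_a), " not present (or empty)")
  if (!nrow(B)) stop("chain ", sQuote(chain_b), " not present (or empty)")
  pairs <- if (method == "brute") {
    .contacts_brute(A, B, dmin, dmax)
  } else {
    .contacts_grid(A, B, dmin, dmax)
  }
  pairs[order(pairs$resno_a, pairs$distance, pairs$resno_b, pairs$atom_a,
              pairs$atom_b), , drop = FALSE]
}

.pair_df <- function(A, B, ia, ib, d) {
  data.frame(resno_a = A$resno[ia], resid_a = A$resid[ia],
             atom_a = A$atom[ia],
             resno_b = B$resno[ib], resid_b = B$resid[ib],
             atom_b = B$atom[ib], distance = d,
             stringsAsFactors = FALSE)
}

.contacts_brute <- function(A, B, dmin, dmax) {
  ax <- as.matrix(A[, c("x", "y", "z")])
  bx <- as.matrix(B[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rep(1, nrow(bx))) +
    outer(rep(1, nrow(ax)), rowSums(bx^2)) - 2 * ax %*% t(bx)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  sel <- which(d >= dmin & d <= dmax, arr.ind = TRUE)
  .pair_df(A, B, sel[, 1L], sel[, 2L], d[sel])
}

.contacts_grid <- function(A, B, dmin, dmax) {
  cell <- dmax
  key <- function(M) {
    ix <- floor(M$x / cell); iy <- floor(M$y / cell); iz <- floor(M$z / cell)
    list(ix = ix, iy = iy, iz = iz,
         id = paste(ix, iy, iz, sep = ","))
  }
  ka <- key(A); kb <- key(B)
  bmap <- split(seq_len(nrow(B)), kb$id)
  ia_all <- integer(); ib_all <- integer(); d_all <- numeric()
  for (i in seq_len(nrow(A))) {
    cand <- integer()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      id <- paste(ka$ix[i] + dx, ka$iy[i] + dy, ka$iz[i] + dz, sep = ",")
      cand <- c(cand, bmap[[id]])
    }
    if (!length(cand)) next
    d <- sqrt((A$x[i] - B$x[cand])^2 + (A$y[i] - B$y[cand])^2 +
                (A$z[i] - B$z[cand])^2)
    hit <- d >= dmin & d <= dmax
    ia_all <- c(ia_all, rep(i, sum(hit)))
    ib_all <- c(ib_all, cand[hit])
    d_all <- c(d_all, d[hit])
  }
  .pair_df(A, B, ia_all, ib_all, d_all)
}

#' Cluster contacting residues into interface regions
#'
#' Sorted residue indices are merged into one region while consecutive
#' indices differ by at most `gap_tol`; each region is reported as its
#' `[min, max]` range in author numbering. With the default tolerance the
#' receptor residues contacting the effector fall into a small number of
#' contiguous interface regions.
#'
#' @param residues Integer residue numbers (chain-A side of the contacts).
#' @param gap_tol Maximum allowed gap between consecutive members of one
#'   region (default 15).
#' @return Data frame with columns `label` (`interface1`, `interface2`,
#'   ...), `start`, `end`. Empty input yields a zero-row frame.
#' @export
cluster_regions <- function(residues, gap_tol = 15L) {
  stopifnot(gap_tol >= 0)
  residues <- sort(unique(as.integer(residues)))
  if (!length(residues))
    return(data.frame(label = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  breaks <- c(0L, which(diff(residues) > gap_tol), length(residues))
  starts <- residues[breaks[-length(breaks)] + 1L]
  ends <- residues[breaks[-1L]]
  data.frame(label = paste0("interface", seq_along(starts)),
             start = starts, end = ends, stringsAsFactors = FALSE)
}
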