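## File I/O: FASTA input, PDB input/output, the DFR v1 restraint text
## format, and key = value config files.

#' Read a single-record FASTA file
#'
#' @param path FASTA file with exactly one record.
#' @return Uppercase one-letter sequence string (validated against the
#'   20-residue alphabet).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  fa <- bio3d::read.fasta(path, rm.dup = FALSE)
  if (nrow(fa$ali) != 1) stop("expected a single-record FASTA file")
  seqc <- toupper(as.vector(fa$ali[1, ]))
  seqc <- seqc[seqc != "-"]
  validate_sequence(paste(seqc, collapse = ""))
}

#' Write a model to a PDB file
#'
#' Writes fixed-width ATOM records for N, CA, C, O, CB (plus H and the SC
#' pseudo-atom on request), chain A, 1-based residue numbering, occupancy
#' 1.00, B-factor 0.00.  Glycine CB/SC rows are skipped.  Output is
#' byte-deterministic for identical models.
#'
#' @param model A `protein_model`.
#' @param path Output path.
#' @param hydrogens Include amide hydrogens.
#' @param sc_pseudo Include the side-chain center as a pseudo-atom `SC`
#'   (a debug dialect; off by default).
#' @return Invisibly, the path.
#' @export
write_pdb <- function(model, path, hydrogens = FALSE, sc_pseudo = FALSE) {
  aa <- strsplit(model$sequence, "")[[1]]
  L <- length(aa)
  slots <- c(1L, 3L, 6L, 7L, 4L)   # N, CA, C, O, CB
  names_out <- c("N", "CA", "C", "O", "CB")
  if (hydrogens) { slots <- c(slots, 2L); names_out <- c(names_out, "H") }
  if (sc_pseudo) { slots <- c(slots, 5L); names_out <- c(names_out, "SC") }
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(L)) {
    for (k in seq_along(slots)) {
      s <- slots[k]
      row <- (i - 1) * 7 + s
      if (!model$present[row]) next
      serial <- serial + 1L
      el <- substr(names_out[k], 1, 1)
      if (names_out[k] == "SC") el <- "C"
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, names_out[k], "", AA3[[aa[i]]], "A", i,
        model$coords[row, 1], model$coords[row, 2], model$coords[row, 3],
        1, 0, el))
    }
  }
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a single-chain PDB file into a protein model
#'
#' Parses with `bio3d::read.pdb`, takes the first alternate location of
#' each atom, requires N/CA/C for every residue (an error names the
#' offending residues otherwise) and rebuilds any missing CB, H, O and SC
#' positions from the backbone by ideal geometry.
#'
#' @param path PDB file (single chain, standard residues).
#' @return A `protein_model`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (length(unique(at$chain)) > 1)
    stop("expected a single-chain PDB file")
  if (any(!is.na(at$alt) & at$alt != "A" & at$alt != "")) {
    at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]
    warning("alternate locations present; keeping the first")
  }
  resno <- unique(at$resno)
  L <- length(resno)
  if (L < 2) stop("fewer than 2 residues in PDB file")
  aa3_to_1 <- setNames(names(AA3), unname(AA3))
  getm <- function(name) {
    m <- matrix(NA_real_, L, 3)
    sel <- at$elety == name
    for (k in which(sel)) {
      i <- match(at$resno[k], resno)
      if (anyNA(m[i, ])) m[i, ] <- c(at$x[k], at$y[k], at$z[k])
    }
    m
  }
  N <- getm("N"); CA <- getm("CA"); C <- getm("C"); O <- getm("O")
  CB <- getm("CB")
  missing_bb <- which(apply(is.na(N) | is.na(CA) | is.na(C), 1, any))
  if (length(missing_bb))
    stop("missing backbone atoms at residue(s): ",
         paste(resno[missing_bb], collapse = ", "))
  res3 <- vapply(resno, function(rn) at$resid[at$resno == rn][1], "")
  if (any(!res3 %in% names(aa3_to_1)))
    stop("non-standard residue(s): ",
         paste(unique(res3[!res3 %in% names(aa3_to_1)]), collapse = ", "))
  sequence <- paste(aa3_to_1[res3], collapse = "")
  place_pseudo_atoms(sequence, N, CA, C, O = O, CB = CB)
}

## --- DFR v1 restraint format ---------------------------------------------
## Plain-text container of named sparse tensors.  Per channel a header
##   #<kind> <L> <nbins> <symmetric 0/1>
## followed by records "i j b p" (0-based residue indices i < j for
## symmetric channels, bin index b, probability p); contacts use b = 0.
## Pairs without records default to the no-interaction pattern.

#' Write a restraint set in the DFR v1 text format
#'
#' @param restraints A `restraint_set`.
#' @param path Output path.
#' @param digits Significant digits written per probability.
#' @param prob_floor Probabilities at or below this threshold are treated
#'   as zero and not written (keeps files sparse).
#' @return Invisibly, the path.
#' @export
write_dfr <- function(restraints, path, digits = 6, prob_floor = 1e-9) {
  L <- restraints$L
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#DFR v1 L=%d", L), con)
  sep <- abs(row(diag(L)) - col(diag(L)))
  for (ch in CHANNEL_NAMES) {
    x <- restraints[[ch]]
    if (is.null(x)) next
    sc <- bin_schema(ch)
    writeLines(sprintf("#%s %d %d %d", ch, L, sc$nbins,
                       as.integer(sc$symmetric)), con)
    if (is_contact_kind(ch)) {
      idx <- which(upper.tri(x) & sep > 1 & x > prob_floor, arr.ind = TRUE)
      if (nrow(idx)) {
        idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
        writeLines(sprintf("%d %d 0 %.*g", idx[, 1] - 1L, idx[, 2] - 1L,
                           digits, x[idx]), con)
      }
    } else {
      nb <- sc$nbins
      keep_pair <- if (sc$symmetric) upper.tri(diag(L)) & sep > 1 else
        sep > 1
      ## pairs carrying the pure no-interaction default are omitted
      default_pair <- x[, , nb] == 1
      rec <- which(x > prob_floor, arr.ind = TRUE)
      ok <- keep_pair[rec[, 1:2, drop = FALSE]] &
        !default_pair[rec[, 1:2, drop = FALSE]]
      rec <- rec[ok, , drop = FALSE]
      if (nrow(rec)) {
        rec <- rec[order(rec[, 1], rec[, 2], rec[, 3]), , drop = FALSE]
        writeLines(sprintf("%d %d %d %.*g", rec[, 1] - 1L, rec[, 2] - 1L,
                           rec[, 3] - 1L, digits, x[rec]), con)
      }
    }
  }
  invisible(path)
}

#' Read a DFR v1 restraint file
#'
#' Unrecorded pairs default to the no-interaction pattern (all mass in
#' the final bin for distances, the no-interaction bin for orientations,
#' probability 0 for contacts).  Histogram normalization is validated.
#'
#' @param path DFR v1 text file.
#' @return A `restraint_set`.
#' @export
read_dfr <- function(path) {
  if (!file.exists(path)) stop("restraint file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#DFR v1"))
    stop("not a DFR v1 file: ", path)
  L <- as.integer(sub(".*L=", "", lines[1]))
  if (is.na(L) || L < 2) stop("invalid length header in DFR file")
  headers <- grep("^#", lines)
  headers <- headers[headers > 1]
  chans <- list()
  bounds <- c(headers, length(lines) + 1L)
  for (k in seq_along(headers)) {
    hd <- strsplit(sub("^#", "", lines[headers[k]]), "\\s+")[[1]]
    ch <- hd[1]
    if (!ch %in% CHANNEL_NAMES)
      stop("unknown channel in restraint file: ", ch)
    sc <- bin_schema(ch)
    if (as.integer(hd[2]) != L)
      stop(sprintf("channel %s: length mismatch", ch))
    if (as.integer(hd[3]) != sc$nbins)
      stop(sprintf("channel %s: expected %d bins, file says %s",
                   ch, sc$nbins, hd[3]))
    body <- lines[seq(headers[k] + 1L, bounds[k + 1] - 1L)]
    body <- body[nzchar(body)]
    if (is_contact_kind(ch)) {
      x <- matrix(0, L, L)
    } else {
      x <- array(0, c(L, L, sc$nbins))
      x[, , sc$nbins] <- 1
    }
    if (length(body)) {
      rec <- read.table(text = body, col.names = c("i", "j", "b", "p"))
      if (any(rec$i < 0 | rec$i >= L | rec$j < 0 | rec$j >= L))
        stop(sprintf("channel %s: residue index out of range", ch))
      if (any(rec$b < 0 | rec$b >= sc$nbins))
        stop(sprintf("channel %s: bin index out of range", ch))
      if (is_contact_kind(ch)) {
        x[cbind(rec$i + 1L, rec$j + 1L)] <- rec$p
        x[cbind(rec$j + 1L, rec$i + 1L)] <- rec$p
      } else {
        touched <- unique(rec[, c("i", "j")])
        x[cbind(rep(touched$i + 1L, sc$nbins),
                rep(touched$j + 1L, sc$nbins),
                rep(seq_len(sc$nbins), each = nrow(touched)))] <- 0
        x[cbind(rec$i + 1L, rec$j + 1L, rec$b + 1L)] <- rec$p
        if (sc$symmetric) {
          x[cbind(rep(touched$j + 1L, sc$nbins),
                  rep(touched$i + 1L, sc$nbins),
                  rep(seq_len(sc$nbins), each = nrow(touched)))] <- 0
          x[cbind(rec$j + 1L, rec$i + 1L, rec$b + 1L)] <- rec$p
        }
      }
    }
    chans[[ch]] <- x
  }
  rs <- do.call(restraint_set, c(list(L = L), chans, list(validate = FALSE)))
  validate_restraints(rs)
  rs
}

## --- config files ---------------------------------------------------------

#' Write a folding configuration as structured text
#'
#' Flat `key = value` lines: the 24 weights as `weight.<term>.<range>`,
#' optimizer settings, selection policy and generic-term switches.
#'
#' @param config A [fold_config()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_config <- function(config, path) {
  ln <- c("# folding configuration",
          sprintf("weight.%s = %g", names(config$weights), config$weights),
          sprintf("m = %d", config$m),
          sprintf("rounds = %d", config$rounds),
          sprintf("steps = %d", config$steps),
          sprintf("c1 = %g", config$c1),
          sprintf("backtrack = %g", config$backtrack),
          sprintf("max_backtracks = %d", config$max_backtracks),
          sprintf("tol_e = %g", config$tol_e),
          sprintf("tol_g = %g", config$tol_g),
          sprintf("conv_window = %d", config$conv_window),
          sprintf("select_cutoff = %g", config$select_cutoff),
          sprintf("d_b = %g", config$d_b),
          sprintf("init = %s", config$init),
          sprintf("seed = %d", config$seed),
          sprintf("hb_on = %d", as.integer(config$generic_on[["hb"]])),
          sprintf("vdw_on = %d", as.integer(config$generic_on[["vdw"]])),
          sprintf("tor_on = %d", as.integer(config$generic_on[["tor"]])))
  writeLines(ln, path)
  invisible(path)
}

#' Read a folding configuration file
#'
#' A reference copy of the default configuration, documenting all 24
#' weights and the optimizer settings, ships at
#' `system.file("extdata", "default_config.cfg", package = "torsionfold")`.
#'
#' @param path `key = value` file written by [write_config()] (unknown
#'   keys are rejected; missing keys keep their defaults).
#' @param base Configuration supplying defaults.
#' @return A [fold_config()].
#' @export
read_config <- function(path, base = fold_config()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- base
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (startsWith(key, "weight.")) {
      wname <- sub("^weight\\.", "", key)
      if (!wname %in% WEIGHT_NAMES) stop("unknown weight in config: ", wname)
      cfg$weights[wname] <- as.numeric(val)
    } else if (key %in% c("m", "rounds", "steps", "max_backtracks",
                          "conv_window", "seed")) {
      cfg[[key]] <- as.integer(val)
    } else if (key %in% c("c1", "backtrack", "tol_e", "tol_g",
                          "select_cutoff", "d_b")) {
      cfg[[key]] <- as.numeric(val)
    } else if (key == "init") {
      cfg$init <- val
    } else if (key %in% c("hb_on", "vdw_on", "tor_on")) {
      cfg$generic_on[[sub("_on$", "", key)]] <- as.integer(val) > 0
    } else stop("unknown config key: ", key)
  }
  validate_weights(cfg$weights)
  cfg
}
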