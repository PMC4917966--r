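# Sequence-level characterization of interfacial amphipathic helices:
# hydrophobic moments, charge statistics, helical wheels and PROSITE-style
# consensus-motif scanning.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Per-residue hydrophobicity scales (dimensionless). Fauchere-Pliska is the
# default (octanol/water partition based, the scale behind common helical
# wheel servers); Eisenberg consensus and Kyte-Doolittle are also registered.
HYDROPHOBICITY_SCALES <- list(
  fauchere_pliska = c(A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
                      Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
                      L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
                      S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22),
  eisenberg = c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
                Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
                L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
                S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08),
  kyte_doolittle = c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                     Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                     L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                     S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
)

#' Hydrophobicity scale lookup
#'
#' @param name one of `"fauchere_pliska"` (default), `"eisenberg"`,
#'   `"kyte_doolittle"`.
#' @return named numeric vector over the 20 standard residues.
#' @export
hydrophobicity_scale <- function(name = "fauchere_pliska") {
  name <- match.arg(name, names(HYDROPHOBICITY_SCALES))
  HYDROPHOBICITY_SCALES[[name]]
}

#' Peptide sequence
#'
#' One-letter protein sequence with 1-based numbering. The 20 standard
#' residues plus `X` (unknown, hydrophobicity 0, uncharged) are accepted.
#'
#' @param residues character string or character vector of one-letter codes.
#' @param id sequence identifier.
#' @param offset numbering offset: the first residue is numbered
#'   `offset + 1` (default 0, i.e. numbering starts at 1).
#' @return object of class `peptide_sequence`.
#' @export
peptide_sequence <- function(residues, id = "seq", offset = 0) {
  res <- if (length(residues) == 1L)
    strsplit(residues, "")[[1L]] else as.character(residues)
  res <- toupper(res)
  bad <- setdiff(unique(res), c(AA20, "X"))
  if (length(bad) > 0L)
    stop("invalid residue letter(s): ", paste(bad, collapse = ", "))
  structure(list(id = id, residues = res, offset = as.integer(offset)),
            class = "peptide_sequence")
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat(sprintf("<peptide_sequence> %s  %d residues (numbered %d-%d)\n  %s\n",
              x$id, length(x$residues), x$offset + 1L,
              x$offset + length(x$residues),
              paste(x$residues, collapse = "")))
  invisible(x)
}

as_residue_vector <- function(seq) {
  if (inherits(seq, "peptide_sequence")) seq$residues
  else peptide_sequence(seq)$residues
}

residue_hydrophobicity <- function(res, scale) {
  h <- unname(scale[res])
  h[res == "X"] <- 0
  if (anyNA(h)) stop("residue(s) missing from the hydrophobicity scale")
  h
}

#' Hydrophobic moment of a helical window
#'
#' Normalized helical hydrophobic moment: residue hydrophobicities are summed
#' as unit vectors spaced `twist` degrees apart around the helical wheel,
#' and the magnitude of the vector sum is divided by the number of residues,
#' \deqn{\mu_H = \frac{1}{N}\left|\sum_n H_n (\cos n\delta, \sin n\delta)\right|.}
#' Interfacial amphipathic helices typically score above 0.45 on the
#' Fauchere-Pliska scale.
#'
#' @param seq a `peptide_sequence`, character string, or residue vector
#'   (the window to evaluate, length >= 3).
#' @param scale hydrophobicity scale name or named numeric vector.
#' @param twist helical twist in degrees per residue (default 100, canonical
#'   alpha-helix).
#' @return list with `mu_h` (normalized moment), `azimuth` (direction of the
#'   hydrophobic face in wheel coordinates, degrees in [0, 360)) and `n`.
#' @export
hydrophobic_moment <- function(seq, scale = "fauchere_pliska", twist = 100) {
  res <- as_residue_vector(seq)
  if (length(res) < 3L) stop("window must contain at least 3 residues")
  if (is.character(scale) && length(scale) == 1L) scale <- hydrophobicity_scale(scale)
  h <- residue_hydrophobicity(res, scale)
  ang <- (seq_along(res) - 1L) * twist * DEG
  mx <- sum(h * cos(ang)); my <- sum(h * sin(ang))
  list(mu_h = sqrt(mx^2 + my^2) / length(res),
       azimuth = (atan2(my, mx) / DEG) %% 360,
       n = length(res))
}

#' Maximum-window hydrophobic moment of a helix
#'
#' Slides a fixed-length window along the sequence and reports the maximum
#' normalized hydrophobic moment, the helix-level summary used for
#' amphipathicity calls (default window 11 residues, about three helical
#' turns).
#'
#' @inheritParams hydrophobic_moment
#' @param window window length in residues.
#' @return list with `mu_h`, `start` (1-based window start in sequence
#'   numbering), `window`, and `azimuth` of the best window.
#' @export
max_hydrophobic_moment <- function(seq, window = 11, scale = "fauchere_pliska",
                                   twist = 100) {
  s <- if (inherits(seq, "peptide_sequence")) seq else peptide_sequence(seq)
  n <- length(s$residues)
  if (n < window) window <- n
  best <- NULL
  for (i in seq_len(n - window + 1L)) {
    m <- hydrophobic_moment(s$residues[i:(i + window - 1L)], scale, twist)
    if (is.null(best) || m$mu_h > best$mu_h) {
      best <- m; best$start <- i + s$offset
    }
  }
  best$window <- as.integer(window)
  best
}

#' Charge statistics of a sequence
#'
#' Net formal charge and percentage of charged residues at neutral pH with
#' the helical-wheel convention: D, E = -1; K, R = +1; histidine neutral;
#' termini uncharged.
#'
#' @param seq a `peptide_sequence`, character string, or residue vector.
#' @return list with `net_charge` (integer), `charged_fraction` (percent)
#'   and counts `n_positive`, `n_negative`.
#' @export
charge_stats <- function(seq) {
  res <- as_residue_vector(seq)
  npos <- sum(res %in% c("K", "R"))
  nneg <- sum(res %in% c("D", "E"))
  list(net_charge = as.integer(npos - nneg),
       charged_fraction = 100 * (npos + nneg) / length(res),
       n_positive = npos, n_negative = nneg)
}

#' Helical wheel coordinates
#'
#' Positions of each residue on the unit helical wheel: residue n (0-based
#' within the window) sits at azimuth `n * twist` degrees, radius 1.
#'
#' @inheritParams hydrophobic_moment
#' @return data.frame with columns `index` (1-based within window),
#'   `residue`, `azimuth` (degrees in [0, 360)), `radius`,
#'   `hydrophobicity`, and `class` ("hydrophobic", "charged", "polar").
#' @export
wheel_coordinates <- function(seq, scale = "fauchere_pliska", twist = 100) {
  res <- as_residue_vector(seq)
  if (is.character(scale) && length(scale) == 1L) scale <- hydrophobicity_scale(scale)
  h <- residue_hydrophobicity(res, scale)
  cls <- ifelse(res %in% c("K", "R", "D", "E"), "charged",
                ifelse(h > 0.5, "hydrophobic", "polar"))
  data.frame(index = seq_along(res),
             residue = res,
             azimuth = ((seq_along(res) - 1L) * twist) %% 360,
             radius = 1,
             hydrophobicity = h,
             class = cls,
             stringsAsFactors = FALSE)
}

#' Compile a PROSITE-style motif
#'
#' Parses a PROSITE-style consensus pattern into per-position residue
#' classes. Supported syntax: single-letter literals, `x` (any residue),
#' `[ABC]` (alternatives), `{ABC}` (exclusions), elements separated by `-`.
#' For example the conserved amphipathic N-terminal consensus
#' `F-[K,R]-x-F-[A,I,L]-x-[K,R]-G`.
#'
#' @param pattern pattern string.
#' @return object of class `sequence_motif` with fields `pattern` (the
#'   original text), `classes` (list of allowed-residue character vectors)
#'   and `width`.
#' @export
sequence_motif <- function(pattern) {
  elements <- strsplit(gsub("\\s+", "", pattern), "-")[[1L]]
  if (length(elements) == 0L) stop("empty motif pattern")
  classes <- vector("list", length(elements))
  for (i in seq_along(elements)) {
    el <- elements[i]
    if (el == "x") {
      classes[[i]] <- c(AA20, "X")
    } else if (grepl("^\\[[A-Za-z,]+\\]$", el)) {
      classes[[i]] <- unique(toupper(strsplit(gsub("[\\[\\],]", "", el,
                                                   perl = TRUE), "")[[1L]]))
    } else if (grepl("^\\{[A-Za-z,]+\\}$", el)) {
      excl <- unique(toupper(strsplit(gsub("[{},]", "", el), "")[[1L]]))
      classes[[i]] <- setdiff(AA20, excl)
    } else if (grepl("^[A-Za-z]$", el)) {
      classes[[i]] <- toupper(el)
    } else {
      stop(sprintf("malformed motif element '%s' at position %d", el, i))
    }
    bad <- setdiff(classes[[i]], c(AA20, "X"))
    if (length(bad) > 0L)
      stop(sprintf("invalid residue letter(s) %s in motif element %d",
                   paste(bad, collapse = ","), i))
  }
  structure(list(pattern = pattern, classes = classes,
                 width = length(classes)),
            class = "sequence_motif")
}

#' @export
format.sequence_motif <- function(x, ...) {
  paste(vapply(x$classes, function(cl) {
    if (length(cl) >= 20L) "x"
    else if (length(cl) == 1L) cl
    else paste0("[", paste(cl, collapse = ","), "]")
  }, character(1L)), collapse = "-")
}

#' @export
print.sequence_motif <- function(x, ...) {
  cat("<sequence_motif>", format(x), sprintf("(width %d)\n", x$width))
  invisible(x)
}

#' Scan a sequence for motif matches
#'
#' Reports all (possibly overlapping) occurrences of a PROSITE-style motif.
#'
#' @param seq a `peptide_sequence`, character string, or residue vector.
#' @param motif a `sequence_motif` or pattern string.
#' @return data.frame with columns `start` (1-based, in sequence numbering),
#'   `end`, and `match` (the matched span); zero rows when nothing matches.
#' @export
motif_scan <- function(seq, motif) {
  if (!inherits(motif, "sequence_motif")) motif <- sequence_motif(motif)
  s <- if (inherits(seq, "peptide_sequence")) seq else peptide_sequence(seq)
  res <- s$residues
  n <- length(res); w <- motif$width
  starts <- integer(0L)
  if (n >= w) {
    for (i in seq_len(n - w + 1L)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        if (!(res[i + j - 1L] %in% motif$classes[[j]])) { ok <- FALSE; break }
      }
      if (ok) starts <- c(starts, i)
    }
  }
  data.frame(start = starts + s$offset,
             end = starts + s$offset + w - 1L,
             match = vapply(starts, function(i)
               paste(res[i:(i + w - 1L)], collapse = ""), character(1L)),
             stringsAsFactors = FALSE)
}

#' Bundled MscL N-terminal sequences
#'
#' N-terminal segments (roughly the first 15 residues) of MscL-family
#' channels used by the amphipathy examples and fixtures. The EcMscL entry
#' is the genuine E. coli sequence; the remaining entries are synthetic
#' representatives patterned on homologue N-termini from several bacterial
#' classes, each carrying the conserved amphipathic consensus.
#'
#' @return named character vector of one-letter sequences.
#' @export
mscl_nterm_sequences <- function() {
  c(EcMscL = "MSIIKEFREFAMRGN",   # Escherichia coli
    MtMscL = "MLKGFKEFLARGN",     # Mycobacterium tuberculosis
    SaMscL = "MLKEFKEFALRGN",     # Staphylococcus aureus
    BsMscL = "MWLKEFKSFAMRGN",    # Bacillus subtilis
    HiMscL = "MSMIREFKEFALRGN",   # Haemophilus influenzae
    PaMscL = "MGMVSEFKQFAVRGN")   # Pseudomonas aeruginosa
}

#' The conserved N-terminal amphipathic consensus motif
#'
#' The consensus motif of the distal N-terminal amphipathic region of
#' bacterial MscL homologues, `F-[K,R]-x-F-[A,I,L]-x-[K,R]-G`, which in
#' EcMscL matches at position 7 (F7...G14).
#'
#' @return a `sequence_motif`.
#' @export
mscl_consensus_motif <- function() sequence_motif("F-[K,R]-x-F-[A,I,L]-x-[K,R]-G")
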