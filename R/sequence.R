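#' Parse a one-letter peptide sequence
#'
#' Builds a `peptide` object from a one-letter residue string, resolving each
#' residue against [residue_table()].  Terminal capping follows the usual
#' synthesis convention for beta-sheet fibrillizing 11-mers: N-terminal
#' acetylation and C-terminal amidation, both on by default, so that the
#' termini carry no charge.
#'
#' @param seq one-letter residue string (standard 20 codes plus `O` for
#'   ornithine).
#' @param id species label, e.g. `"CATCH(6+)"`.  Defaults to the sequence
#'   itself.
#' @param n_term_acetylated,c_term_amidated logical cap flags.  An uncapped
#'   N-terminus contributes +1 to the net charge, an uncapped C-terminus -1.
#' @return An object of class `peptide`: a list with `id`, `residues`
#'   (a data.frame of per-residue parameters), `n_term_acetylated`,
#'   `c_term_amidated`.
#' @examples
#' p <- parse_sequence("EQEFEWEFEQE")
#' net_charge(p)  # -6
#' @export
parse_sequence <- function(seq, id = seq,
                           n_term_acetylated = TRUE,
                           c_term_amidated = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 2L) {
    stop("sequence must have at least 2 residues (got ", nchar(seq), ")",
         call. = FALSE)
  }
  codes <- strsplit(toupper(seq), "")[[1]]
  rt <- residue_table()
  bad <- which(!codes %in% rt$code)
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue code '%s' at position %d",
                 codes[bad[1]], bad[1]), call. = FALSE)
  }
  res <- rt[codes, ]
  rownames(res) <- NULL
  structure(
    list(id = id, residues = res,
         n_term_acetylated = isTRUE(n_term_acetylated),
         c_term_amidated = isTRUE(c_term_amidated)),
    class = "peptide"
  )
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("peptide %s: %s%s%s (length %d, net charge %+d)\n",
              x$id,
              if (x$n_term_acetylated) "Ac-" else "H-",
              paste(x$residues$code, collapse = ""),
              if (x$c_term_amidated) "-NH2" else "-OH",
              nrow(x$residues), net_charge(x)))
  invisible(x)
}

#' @export
length.peptide <- function(x) nrow(x$residues)

#' One-letter sequence string of a peptide
#' @param p a `peptide`.
#' @return character scalar.
#' @export
sequence_string <- function(p) {
  stopifnot(inherits(p, "peptide"))
  paste(p$residues$code, collapse = "")
}

#' Formal net charge of a peptide at neutral pH
#'
#' Sum of per-residue formal charges (K/R/O = +1, E/D = -1, H = 0), plus the
#' terminal contributions: a free (unacetylated) N-terminus counts +1 and a
#' free (unamidated) C-terminus counts -1; capped termini contribute nothing.
#' No pKa titration is performed: lysines and glutamates are taken as fully
#' protonated and deprotonated respectively, the regime in which Coulombic
#' design arguments for charge-complementary co-assembly are made.
#'
#' @param p a `peptide` from [parse_sequence()].
#' @return integer net charge in units of e.
#' @examples
#' net_charge(parse_sequence("QQOFOWOFOQQ"))  # +4, ornithine is cationic
#' @export
net_charge <- function(p) {
  stopifnot(inherits(p, "peptide"))
  q <- sum(p$residues$formal_charge)
  if (!p$n_term_acetylated) q <- q + 1L
  if (!p$c_term_amidated)  q <- q - 1L
  as.integer(q)
}

#' Ratio of Coulombic attraction between two peptide pairs
#'
#' For two pairs of oppositely charged peptides at equal separation,
#' Coulomb's law gives attractive forces proportional to the product of the
#' net charges, so the ratio of attraction magnitudes is
#' \eqn{|q_{1A} q_{1B}| / |q_{2A} q_{2B}|}.  For the (+6, -6) pair versus the
#' (+4, -4) pair this is 36/16 = 2.25, the classic argument for why more
#' highly charged complementary peptides find each other faster.
#'
#' @param pair1,pair2 each a list of two `peptide` objects (or a numeric
#'   vector of two net charges).
#' @return dimensionless ratio of Coulombic force magnitudes.
#' @examples
#' p6 <- list(parse_sequence("KQKFKWKFKQK"), parse_sequence("EQEFEWEFEQE"))
#' p4 <- list(parse_sequence("QQKFKWKFKQQ"), parse_sequence("QQEFEWEFEQQ"))
#' coulomb_attraction_ratio(p6, p4)  # 2.25
#' @export
coulomb_attraction_ratio <- function(pair1, pair2) {
  q1 <- pair_charges(pair1)
  q2 <- pair_charges(pair2)
  num <- abs(q1[1] * q1[2])
  den <- abs(q2[1] * q2[2])
  if (num == 0) {
    stop("numerator pair has a zero charge product", call. = FALSE)
  }
  if (den == 0) {
    stop("denominator pair has a zero charge product", call. = FALSE)
  }
  num / den
}

pair_charges <- function(pair) {
  if (is.numeric(pair) && length(pair) == 2L) return(pair)
  if (is.list(pair) && length(pair) == 2L &&
      all(vapply(pair, inherits, logical(1), "peptide"))) {
    return(vapply(pair, net_charge, numeric(1)))
  }
  stop("a pair must be two peptide objects or two numeric net charges",
       call. = FALSE)
}

#' Heuristic self-association propensity of a charged peptide
#'
#' Rule-of-thumb classifier for whether a charge-bearing beta-sheet peptide
#' resists self-association in physiological buffer, encoding the empirical
#' observation that two glutamates suffice to prevent self-assembly whereas
#' two lysines do not (three or more are needed on the cationic side):
#'
#' * `"resists"`  - >= 3 cationic residues (K/R/O), or >= 2 anionic residues
#'   (E/D), with no residues of the opposite charge present;
#' * `"prone"`    - exactly 2 cationic residues and no anionic residues;
#' * `"indeterminate"` - anything else (zwitterionic or weakly charged
#'   sequences fall outside the rule).
#'
#' This is an empirical heuristic, not a physical model; it makes no
#' statement about co-assembly with a complementary partner.
#'
#' @param p a `peptide`.
#' @return character scalar: `"resists"`, `"prone"` or `"indeterminate"`.
#' @export
self_association_risk <- function(p) {
  stopifnot(inherits(p, "peptide"))
  n_pos <- sum(p$residues$formal_charge > 0)
  n_neg <- sum(p$residues$formal_charge < 0)
  if (n_pos >= 3L && n_neg == 0L) return("resists")
  if (n_neg >= 2L && n_pos == 0L) return("resists")
  if (n_pos == 2L && n_neg == 0L) return("prone")
  "indeterminate"
}

#' Read peptides from a FASTA file
#'
#' Headers may carry `key=value` tags after the identifier; recognised tags
#' are `acetylated` and `amidated` (`true`/`false`, default `true`), so a
#' record like `>CATCH(6+) acetylated=true amidated=true` round-trips the cap
#' flags.  Sequences may span multiple lines.
#'
#' @param path FASTA file path.
#' @return named list of `peptide` objects.
#' @seealso [catch_sequences()] for the bundled synthetic sequence set.
#' @export
read_peptide_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path, call. = FALSE)
  idx <- cumsum(hdr)
  out <- list()
  for (k in seq_len(max(idx))) {
    block <- lines[idx == k]
    header <- sub("^>", "", block[1])
    seq <- paste(gsub("\\s", "", block[-1]), collapse = "")
    fields <- strsplit(trimws(header), "\\s+")[[1]]
    id <- fields[1]
    tags <- fields[-1]
    get_tag <- function(name, default) {
      m <- grep(paste0("^", name, "="), tags, value = TRUE)
      if (length(m) == 0) return(default)
      tolower(sub(".*=", "", m[1])) %in% c("true", "t", "1", "yes")
    }
    out[[id]] <- parse_sequence(seq, id = id,
                                n_term_acetylated = get_tag("acetylated", TRUE),
                                c_term_amidated = get_tag("amidated", TRUE))
  }
  out
}

#' Write peptides to a FASTA file
#'
#' @param peptides list of `peptide` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(peptides, path) {
  lines <- unlist(lapply(peptides, function(p) {
    c(sprintf(">%s acetylated=%s amidated=%s", p$id,
              tolower(p$n_term_acetylated), tolower(p$c_term_amidated)),
      sequence_string(p))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Bundled charge-variant sequence set
#'
#' Loads the package's bundled 11-mer sequence file.  The CATCH-like entries
#' are *synthetic stand-ins*: they are generated from the Q/F scaffold
#' `QQQFQWQFQQQ` by substituting K (cationic) or E (anionic) at glutamine
#' positions, the same construction that underlies published
#' charge-complementary designs (e.g. EQEFEWEFEQE at -6 and QQOFOWOFOQQ at
#' +4); they are not transcribed from any published supplementary table.
#' The zwitterionic parent `Q11` entry is the published Q11 sequence.
#' Use [read_peptide_fasta()] on your own file to substitute exact sequences.
#'
#' @return named list of `peptide` objects, including `CATCH_like(2+)`,
#'   `CATCH_like(2-)`, `CATCH_like(4+)`, `CATCH_like(4-)`, `CATCH_like(6+)`,
#'   `CATCH_like(6-)` and `Q11`.
#' @export
catch_sequences <- function() {
  path <- system.file("extdata", "catch_like_sequences_synthetic.fasta",
                      package = "dmdpep", mustWork = TRUE)
  read_peptide_fasta(path)
}
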