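#' Parse a peptaibol sequence from a three-letter-code token string
#'
#' Tokens may be separated by hyphens and/or whitespace. An optional leading
#' \code{"Ac"} token marks N-terminal acetylation; positions are assigned
#' 1-based from the first residue after it. The ambiguity codes \code{Lxx}
#' and \code{Vxx} (Leu/Ile and Val/Iva, indistinguishable by nominal mass)
#' are resolved to \code{Leu} and \code{Val}; the original tokens are kept in
#' the \code{original} field.
#'
#' @param text Token string, e.g. \code{"Ac-Aib-Ala-...-Pheol"}.
#' @param name Optional sequence name carried on the object.
#' @return An object of class \code{"peptaibol"}: a list with elements
#'   \code{name}, \code{residues} (character vector, positions R1..RL),
#'   \code{original} (tokens before Lxx/Vxx resolution), \code{acetylated},
#'   \code{terminal_alcohol} and \code{group} (\code{"unknown"} until
#'   \code{\link{classify_group}} is applied).
#' @examples
#' p <- parse_sequence("Ac-Aib-Pro-Pheol")
#' p$residues
#' @seealso \code{\link{fragment_ions}}, \code{\link{classify_group}}
#' @export
parse_sequence <- function(text, name = "") {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- strsplit(trimws(text), "[-[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop("empty sequence string")
  }
  acetylated <- identical(tokens[1L], "Ac")
  if (acetylated) tokens <- tokens[-1L]
  if (length(tokens) == 0L) {
    stop("sequence contains no residues after the 'Ac' prefix")
  }
  resolved <- ifelse(tokens == "Lxx", "Leu",
              ifelse(tokens == "Vxx", "Val", tokens))
  known <- names(residue_masses())
  bad <- which(!resolved %in% known)
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue code '%s' at position %d",
                 tokens[bad[1L]], bad[1L]))
  }
  structure(
    list(
      name             = name,
      residues         = resolved,
      original         = tokens,
      acetylated       = acetylated,
      terminal_alcohol = resolved[length(resolved)] %in% .AMINO_ALCOHOLS,
      group            = "unknown"
    ),
    class = "peptaibol"
  )
}

#' @export
print.peptaibol <- function(x, ...) {
  cat(sprintf("Peptaibol sequence%s (L = %d)\n",
              if (nzchar(x$name)) paste0(" ", x$name) else "",
              length(x$residues)))
  cat(" ", paste0(c(if (x$acetylated) "Ac", x$residues), collapse = "-"),
      "\n", sep = "")
  cat(sprintf("  acetylated: %s, amino-alcohol terminus: %s, group: %s\n",
              x$acetylated, x$terminal_alcohol, x$group))
  invisible(x)
}

#' @export
length.peptaibol <- function(x) length(x$residues)

#' Read a peptaibol sequence file
#'
#' One record per line, \code{name<TAB>Ac-Xxx-Xxx-...}; blank lines and lines
#' starting with \code{#} are skipped. The 12 reference sequences ship with
#' the package (see examples).
#'
#' @param path Path to the sequence file.
#' @return Named list of \code{"peptaibol"} objects.
#' @examples
#' seqs <- read_sequences(system.file("extdata", "peptaibol_sequences.tsv",
#'                                    package = "peptaifold"))
#' names(seqs)
#' @export
read_sequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no sequence records in ", path)
  out <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) != 2L) {
      stop("malformed record (expected name<TAB>sequence): ", ln)
    }
    parse_sequence(parts[2L], name = parts[1L])
  })
  names(out) <- vapply(out, function(p) p$name, character(1))
  if (anyDuplicated(names(out))) stop("duplicate sequence names in ", path)
  out
}

#' Locate the labile Aib-Pro bond
#'
#' Returns the 1-based position of the first Aib directly followed by Pro.
#' The Aib-Pro amide bond is the preferred fragmentation site of peptaibols
#' in ESI-MS and the helix-kink hinge; in the 20-residue reference sequences
#' it sits at R13-R14, yielding the b13/y7p ion pair.
#'
#' @param seq A \code{"peptaibol"} object.
#' @return Integer position n such that residue n is Aib and n+1 is Pro.
#' @export
find_labile_bond <- function(seq) {
  stopifnot(inherits(seq, "peptaibol"))
  r <- seq$residues
  L <- length(r)
  if (L >= 2L) {
    hits <- which(r[-L] == "Aib" & r[-1L] == "Pro")
    if (length(hits) > 0L) return(hits[1L])
  }
  stop("no labile Aib-Pro bond in sequence ",
       if (nzchar(seq$name)) seq$name else "<unnamed>")
}

#' Nominal b/y fragment-ion masses for a backbone cleavage
#'
#' Computes the nominal masses of the N-terminal b ion and C-terminal y ion
#' formed by cleaving the amide bond after position \code{cleave_after}.
#' Convention (validated against all published pairs for the reference
#' sequences): the b ion is the acetyl-capped acylium,
#' \eqn{b = \sum_{i=1}^{n} m_i + 43}; the y ion is the protonated amine with
#' the C-terminal amino alcohol counted at its full molecular nominal mass,
#' \eqn{y = \sum_{i=n+1}^{L-1} m_i + m(\mathrm{alcohol}) + 1}.
#'
#' @param seq A \code{"peptaibol"} object; must be acetylated with an
#'   amino-alcohol terminus (the convention is undefined otherwise).
#' @param cleave_after Cleavage position n, \code{1 <= n < L}. Default: the
#'   labile Aib-Pro bond from \code{\link{find_labile_bond}}.
#' @return Named integer vector \code{c(b = ..., y = ...)} in Da.
#' @examples
#' p <- parse_sequence("Ac-Gly-Pheol")
#' fragment_ions(p, cleave_after = 1)  # b = 57 + 43, y = 151 + 1
#' @export
fragment_ions <- function(seq, cleave_after = find_labile_bond(seq)) {
  stopifnot(inherits(seq, "peptaibol"))
  if (!seq$acetylated) {
    stop("fragment-ion convention requires an acetylated N-terminus")
  }
  if (!seq$terminal_alcohol) {
    stop("fragment-ion convention requires a C-terminal amino alcohol")
  }
  L <- length(seq$residues)
  n <- as.integer(cleave_after)
  if (length(n) != 1L || is.na(n) || n < 1L || n >= L) {
    stop("cleave_after must satisfy 1 <= n < L = ", L)
  }
  m <- residue_masses()[seq$residues]
  b <- sum(m[seq_len(n)]) + .MASS_ACETYL_B
  # residues n+1 .. L-1 plus the whole amino-alcohol molecule plus a proton
  mid <- if (n + 1L <= L - 1L) sum(m[seq(n + 1L, L - 1L)]) else 0L
  y <- mid + m[[L]] + .MASS_PROTON
  c(b = as.integer(b), y = as.integer(y))
}

#' Classify a peptaibol into sequence group A or B
#'
#' Inspects the four-residue window ending at the Pro of the labile Aib-Pro
#' bond (positions R11-R14 in the 20-residue reference sequences):
#' Gly-Leu-Aib-Pro gives group \code{"A"}, Gly-Aib-Aib-Pro gives group
#' \code{"B"}, anything else (including sequences without an Aib-Pro bond)
#' gives \code{"unknown"}. Group A carries the bulky Leu at the position
#' before the Aib-Pro kink; group B carries a second Aib there.
#'
#' @param seq A \code{"peptaibol"} object.
#' @return The input object with \code{group} set to "A", "B" or "unknown".
#' @export
classify_group <- function(seq) {
  stopifnot(inherits(seq, "peptaibol"))
  pos <- tryCatch(find_labile_bond(seq), error = function(e) NA_integer_)
  grp <- "unknown"
  if (!is.na(pos) && pos >= 3L) {
    window <- seq$residues[(pos - 2L):(pos + 1L)]
    if (identical(window, c("Gly", "Leu", "Aib", "Pro"))) grp <- "A"
    if (identical(window, c("Gly", "Aib", "Aib", "Pro"))) grp <- "B"
  }
  seq$group <- grp
  seq
}

#' Read strain production profiles
#'
#' Long-format TSV with columns \code{strain}, \code{group}, \code{peptaibol},
#' \code{percent} (percentage of the strain's total peptaibol production).
#' The reference profiles of the six producer strains ship with the package.
#'
#' @param path Path to the profile table. Defaults to the packaged table.
#' @return data.frame with the four columns above.
#' @export
read_production_profiles <- function(path = system.file("extdata",
    "production_profiles.tsv", package = "peptaifold")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "group", "peptaibol", "percent")
  if (!all(need %in% names(df))) {
    stop("profile table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$percent < 0 | df$percent > 100)) {
    stop("production percentages must lie in [0, 100]")
  }
  df
}

#' Aggregate production percentages over a set of peptaibols
#'
#' Sums the production percentages of the named peptaibols for one strain,
#' e.g. the total share of a sequence group in a strain's peptaibol output.
#' Names absent from the strain's profile contribute 0 with a warning.
#'
#' @param profile data.frame as from \code{\link{read_production_profiles}},
#'   already restricted to (or filtered here by) one strain.
#' @param names Character vector of peptaibol names to sum; default all.
#' @param strain Optional strain id to filter \code{profile} by.
#' @return Total percentage, rounded to 2 decimals.
#' @examples
#' prof <- read_production_profiles()
#' aggregate_production(prof, strain = "SZMC 1775")  # 96.34
#' @export
aggregate_production <- function(profile, names = NULL, strain = NULL) {
  if (!is.null(strain)) profile <- profile[profile$strain == strain, ]
  if (is.null(names)) names <- profile$peptaibol
  if (length(names) == 0L) return(0)
  missing <- setdiff(names, profile$peptaibol)
  if (length(missing) > 0L) {
    warning("not in profile (treated as 0): ", paste(missing, collapse = ", "))
  }
  round(sum(profile$percent[profile$peptaibol %in% names]), 2)
}
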