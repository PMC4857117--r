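#' @importFrom tibble tibble as_tibble
NULL

# Length of the circular human mitogenome in rCRS coordinates.
MT_LENGTH <- 16569L

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

variant_token_re <- "^(@?)([0-9]+)(?:\\.([0-9]+)([ACGT]+)|([ACGTDRY]))?$"

#' Parse mtDNA variants written in position-based mutation notation
#'
#' Tokens follow the conventions used for mutation-annotated mtDNA trees:
#' a bare position (`"16126"`) is a transition; a base suffix (`"16265A"`)
#' is a transversion to that base; `"d"` marks a deletion (`"522d"`);
#' `"R"`/`"Y"` mark point heteroplasmies; a leading `"@"` marks a
#' reversion (`"@152"`); insertions carry a dot, the number of inserted
#' bases and the inserted sequence (`"573.1C"`).
#'
#' @param tokens Character vector of notation tokens.
#' @return A tibble with one row per token: `token` (canonical rendering),
#'   `position`, `kind` (`transition`, `transversion`, `insertion`,
#'   `deletion`), `derived_base`, `insert_index`, `insert_seq`,
#'   `is_reversion`, `is_heteroplasmy`.
#' @examples
#' parse_variant(c("16126", "522d", "573.1C", "@152", "16265A", "152Y"))
#' @export
parse_variant <- function(tokens) {
  tokens <- toupper(trimws(as.character(tokens)))
  tokens <- sub("^@", "@", tokens) # no-op, keeps @ canonical
  bad <- tokens == "" | !grepl(variant_token_re, tokens)
  if (any(bad)) {
    stop("malformed variant token(s): ", paste(unique(tokens[bad]), collapse = ", "))
  }
  m <- regmatches(tokens, regexec(variant_token_re, tokens))
  rev_flag <- vapply(m, function(x) x[2] == "@", logical(1))
  pos <- as.integer(vapply(m, `[`, character(1), 3))
  ins_idx <- vapply(m, `[`, character(1), 4)
  ins_seq <- vapply(m, `[`, character(1), 5)
  suffix <- vapply(m, `[`, character(1), 6)

  out_of_range <- pos < 1L | pos > MT_LENGTH
  if (any(out_of_range)) {
    stop("variant position out of range 1..", MT_LENGTH, ": ",
         paste(unique(tokens[out_of_range]), collapse = ", "))
  }

  kind <- ifelse(ins_idx != "", "insertion",
          ifelse(suffix == "D", "deletion",
          ifelse(suffix %in% c("A", "C", "G", "T"), "transversion", "transition")))
  het <- suffix %in% c("R", "Y")
  derived <- ifelse(suffix %in% c("A", "C", "G", "T", "R", "Y"), suffix, NA_character_)

  out <- tibble(
    token = tokens,
    position = pos,
    kind = kind,
    derived_base = derived,
    insert_index = ifelse(ins_idx == "", NA_integer_, as.integer(ins_idx)),
    insert_seq = ifelse(ins_seq == "", NA_character_, ins_seq),
    is_reversion = rev_flag,
    is_heteroplasmy = het
  )
  out$token <- render_variant(out)
  out
}

#' Render parsed variants back to canonical notation tokens
#'
#' Inverse of [parse_variant()]: `render_variant(parse_variant(x))` equals
#' the normalized form of `x`.
#'
#' @param variants A tibble as returned by [parse_variant()].
#' @return Character vector of canonical tokens.
#' @export
render_variant <- function(variants) {
  suffix <- ifelse(variants$kind == "insertion",
                   paste0(".", variants$insert_index, variants$insert_seq),
            ifelse(variants$kind == "deletion", "d",
            ifelse(is.na(variants$derived_base), "", variants$derived_base)))
  paste0(ifelse(variants$is_reversion, "@", ""), variants$position, suffix)
}

#' @rdname parse_variant
#' @details `normalize_variant()` is a convenience wrapper returning the
#'   canonical token strings themselves.
#' @export
normalize_variant <- function(tokens) render_variant(parse_variant(tokens))

# position of each token, ignoring the reversion mark
variant_position <- function(tokens) {
  as.integer(sub("^@?([0-9]+).*$", "\\1", tokens))
}

variant_is_indel <- function(tokens) {
  grepl("^@?[0-9]+(\\.[0-9]+[ACGT]+|[dD])$", tokens)
}

# canonical ordering: by position, then insertions after substitutions,
# then token string (stable and human-readable on tree branches)
sort_variants <- function(tokens) {
  if (length(tokens) == 0) return(character(0))
  pos <- variant_position(tokens)
  ins <- variant_is_indel(tokens) & grepl("\\.", tokens)
  tokens[order(pos, ins, tokens)]
}

#' Site-exclusion policy for mtDNA variant profiles
#'
#' Encodes the sites conventionally left out of mtDNA phylogenies and
#' clade diagnosis: the hypervariable np 16519 transition, length
#' variation in the poly-C stretches around nps 309 and 315, the AC
#' indels around nps 515--522, the unreliable np 60 (ignored when
#' identifying clades), and the hypervariable 16182C/16183C
#' transversions (left out of molecular dating).
#'
#' @param excluded_positions Positions dropped in every context.
#' @param cstretch_zone Positions whose indel tokens are treated as poly-C
#'   length variation (phylogeny context).
#' @param ac_indel_zone Positions whose indel tokens are treated as the
#'   515--522 AC repeat variation (phylogeny context). Profiles report
#'   these variously as e.g. 522d or 523d, so the zone is a window.
#' @param clade_id_positions Additional positions ignored when
#'   identifying clades.
#' @param dating_tokens Hypervariable substitution tokens excluded from
#'   dating.
#' @return An object of class `exclusion_policy`.
#' @export
exclusion_policy <- function(excluded_positions = 16519L,
                             cstretch_zone = 302:316,
                             ac_indel_zone = 513:524,
                             clade_id_positions = 60L,
                             dating_tokens = c("16182C", "16183C")) {
  structure(
    list(
      excluded_positions = as.integer(excluded_positions),
      cstretch_zone = as.integer(cstretch_zone),
      ac_indel_zone = as.integer(ac_indel_zone),
      clade_id_positions = as.integer(clade_id_positions),
      dating_tokens = toupper(dating_tokens)
    ),
    class = "exclusion_policy"
  )
}

#' Apply site exclusions to a variant profile
#'
#' Filters a set of variant tokens according to the analysis context:
#' * `"phylogeny"`: drops the globally excluded positions (np 16519 by
#'   default) plus indel tokens in the poly-C stretch and AC-repeat zones;
#' * `"clade_id"`: as `"phylogeny"`, additionally ignoring np 60;
#' * `"dating"`: drops the globally excluded positions and the
#'   hypervariable 16182C/16183C tokens (indels are kept; whether to
#'   count them in rho is decided at counting time).
#'
#' The operation is idempotent and returns a subset of its input.
#'
#' @param tokens Character vector of variant tokens.
#' @param policy An [exclusion_policy()].
#' @param context One of `"phylogeny"`, `"clade_id"`, `"dating"`.
#' @return The filtered character vector.
#' @examples
#' apply_exclusions(c("263", "309.1C", "315.1C", "522d", "16519", "16126"),
#'                  context = "phylogeny")
#' @export
apply_exclusions <- function(tokens, policy = exclusion_policy(),
                             context = c("phylogeny", "clade_id", "dating")) {
  context <- match.arg(context)
  if (length(tokens) == 0) return(character(0))
  tokens <- trimws(tokens)
  pos <- variant_position(tokens)
  indel <- variant_is_indel(tokens)
  drop <- pos %in% policy$excluded_positions
  if (context %in% c("phylogeny", "clade_id")) {
    drop <- drop | (indel & pos %in% c(policy$cstretch_zone, policy$ac_indel_zone))
  }
  if (context == "clade_id") {
    drop <- drop | pos %in% policy$clade_id_positions
  }
  if (context == "dating") {
    drop <- drop | sub("^@", "", tokens) %in% policy$dating_tokens
  }
  tokens[!drop]
}

is_transition_pair <- function(a, b) {
  (a %in% PURINES & b %in% PURINES) | (a %in% PYRIMIDINES & b %in% PYRIMIDINES)
}

#' Call variants from a reference-aligned sequence
#'
#' Compares a sample sequence to its reference in reference coordinates
#' and returns the differences in mutation notation. Both strings are
#' aligned column-by-column: a `-` in the sample is a deletion; columns
#' where the reference carries `-` are insertion columns (the inserted
#' bases are reported after the preceding reference position). `R`/`Y`
#' in the sample at a reference purine/pyrimidine are reported as point
#' heteroplasmies. Alignment itself is out of scope: sequences must
#' already be in reference coordinates.
#'
#' @param sequence Sample sequence (single string, aligned).
#' @param reference Reference sequence (single string, same length;
#'   may contain `-` columns accommodating sample insertions).
#' @return Character vector of canonical variant tokens.
#' @examples
#' call_variants("ACGT", "ACGT")  # identical: no variants
#' call_variants("ATGT", "ACGT")  # C->T at np 2: transition "2"
#' call_variants("AAGT", "ACGT")  # C->A at np 2: transversion "2A"
#' @export
call_variants <- function(sequence, reference) {
  s <- strsplit(toupper(sequence), "")[[1]]
  r <- strsplit(toupper(reference), "")[[1]]
  if (length(s) != length(r)) {
    stop("sequence and reference have different aligned lengths (",
         length(s), " vs ", length(r), ")")
  }
  ok <- s %in% c("A", "C", "G", "T", "R", "Y", "N", "-")
  if (!all(ok)) {
    stop("non-IUPAC character(s) in sequence: ",
         paste(unique(s[!ok]), collapse = ", "))
  }
  tokens <- character(0)
  pos <- 0L
  i <- 1L
  n <- length(r)
  while (i <= n) {
    if (r[i] == "-") {
      # run of insertion columns after reference position `pos`
      j <- i
      while (j <= n && r[j] == "-") j <- j + 1L
      ins <- s[i:(j - 1L)]
      ins <- ins[ins != "-"]
      if (length(ins) > 0) {
        tokens <- c(tokens, paste0(pos, ".", length(ins), paste(ins, collapse = "")))
      }
      i <- j
      next
    }
    pos <- pos + 1L
    if (s[i] == "-") {
      tokens <- c(tokens, paste0(pos, "d"))
    } else if (s[i] != r[i] && s[i] != "N") {
      if (s[i] %in% c("R", "Y")) {
        tokens <- c(tokens, paste0(pos, s[i]))
      } else if (is_transition_pair(s[i], r[i])) {
        tokens <- c(tokens, as.character(pos))
      } else {
        tokens <- c(tokens, paste0(pos, s[i]))
      }
    }
    i <- i + 1L
  }
  sort_variants(tokens)
}
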