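# Internal helpers shared across modules.

# Canonical residue normalization: uppercase, RNA U folded to DNA T,
# '.' gaps folded to '-'.  All pairwise comparisons go through this.
.normChars <- function(x) {
  chartr("uU.", "TT-", toupper(x))
}

.degap <- function(x) {
  gsub("[-.]", "", x)
}

# Degapped, normalized string -- the identity used for content-preservation
# checks and snippet dereplication.
.normDegap <- function(x) {
  .degap(.normChars(x))
}

.isGapChar <- function(ch) ch == "-" | ch == "."

# Character matrix view of an alignment (rows = records, cols = columns).
.alnCharMat <- function(aln) {
  seqs <- aln@seqs
  if (length(seqs) == 0L) {
    return(matrix(character(0), nrow = 0L, ncol = 0L))
  }
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

# Integer encoding of a normalized alignment: gap = 0L, residues mapped to
# small positive codes (distinct per character).  Used by the PSI kernel.
.encodeAln <- function(aln) {
  m <- .alnCharMat(aln)
  if (nrow(m) == 0L) return(matrix(integer(0), 0L, 0L))
  norm <- chartr("uU.", "TT-", toupper(m))
  alphabet <- c("-", "A", "C", "G", "T", "N",
                "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  code <- match(norm, alphabet)
  code[is.na(code)] <- length(alphabet) + match(norm[is.na(code)], unique(norm[is.na(code)]))
  enc <- matrix(as.integer(code) - 1L, nrow = nrow(m),
                dimnames = list(rownames(m), NULL))
  enc
}

# Locale-independent lexicographic ranks of ids (radix sort order), used for
# deterministic tie-breaking in clustering and ordering of cluster output.
.lexRank <- function(ids) {
  ord <- order(ids, method = "radix")
  rk <- integer(length(ids))
  rk[ord] <- seq_along(ids)
  rk
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

.assertFraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a single fraction in [0, 1]", call. = FALSE)
  invisible(x)
}
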