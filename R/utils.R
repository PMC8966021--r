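#' @include AllClasses.R
NULL

# Derive a deterministic per-stage seed from the master seed, so each
# simulation stage can be regenerated independently of the others.
# Kept below 2^31 - 1 (R integers are 32-bit).
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483629)
}

# Kyte-Doolittle hydropathy scale; X is tolerated and scored 0.
.kdScale <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
  X =  0)

.aaAlphabet <- names(.kdScale)

# Coerce a protein sequence argument to a single uppercase character string
# and validate its alphabet.
.checkProtein <- function(sequence) {
  if (methods::is(sequence, "AAString") || methods::is(sequence, "AAStringSet"))
    sequence <- as.character(sequence)
  if (length(sequence) != 1) stop("a single protein sequence is required")
  s <- toupper(sequence)
  if (!nzchar(s)) stop("empty protein sequence")
  letters <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(letters), .aaAlphabet)
  if (length(bad))
    stop("illegal residue character(s): ", paste(bad, collapse = ", "))
  s
}

# Min-max scale a numeric vector to [0, 1]; constant vectors map to 0.
.minMax <- function(x) {
  r <- range(x)
  if (r[2] - r[1] == 0) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

.revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
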