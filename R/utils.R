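# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# field separator for split keys; cannot occur in sane taxon labels
.KSEP <- "\x1f"

.assert <- function(cond, msg, ...) {
  if (!cond) stop(sprintf(msg, ...), call. = FALSE)
}

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All randomness in the package flows from one master seed through named
#' substreams, so any stage (species tree, per-locus gene trees, sequences,
#' missingness masks) can be replayed independently.
#'
#' @param master integer master seed.
#' @param name character stream name.
#' @return an integer seed in \code{[1, 2^31 - 2]}.
#' @export
derive_seed <- function(master, name) {
  .assert(is.numeric(master) && length(master) == 1, "master seed must be a single number")
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer(((abs(master) %% 50021) * 40009 + h * 2477) %% 2147483559 + 1)
}

# tips descending from every node (indices into tip labels for tips)
.tips_below <- function(phy) {
  n <- length(phy$tip.label)
  desc <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (r in seq_len(nrow(eo))) {
    desc[[eo[r, 1L]]] <- c(desc[[eo[r, 1L]]], desc[[eo[r, 2L]]])
  }
  desc
}
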