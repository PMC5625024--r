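#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test cutree dist fisher.test hclust p.adjust
#'   phyper prcomp rnorm runif sd setNames wilcox.test as.dist
#' @importFrom utils head read.delim write.table
NULL

# Stage-name -> offset table used to derive per-stage seeds from one master
# seed. Offsets are arbitrary but fixed so a master seed determines every
# stage stream; kept well below 2^31.
.stage_offsets <- c(
  interactome = 101L, module = 211L, signatures = 307L, expression = 401L,
  annotations = 503L, probes = 601L, rankprod = 701L, es = 809L,
  proximity = 907L, synergy = 1009L
)

#' Derive a deterministic stage seed from a master seed
#'
#' All stochastic stages draw their RNG seed from one master seed plus a fixed
#' per-stage offset, so a single integer reproduces an entire run while stages
#' remain independently re-runnable.
#'
#' @param master integer master seed.
#' @param stage stage name (one of the pipeline stages) or an integer offset.
#' @param index optional extra index (e.g. dataset number) folded in.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  off <- if (is.character(stage)) {
    if (!stage %in% names(.stage_offsets)) {
      stop("unknown stage: ", stage, call. = FALSE)
    }
    .stage_offsets[[stage]]
  } else {
    as.integer(stage)
  }
  as.integer((as.numeric(master) * 7919 + off * 104729 + index * 131) %%
    (.Machine$integer.max - 1))
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
      call. = FALSE
    )
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(as.numeric(x))
}

assert_number <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.finite(x) || x < min) {
    stop(sprintf("'%s' must be a single finite number >= %s", name, min),
      call. = FALSE
    )
  }
  invisible(as.numeric(x))
}

# Benjamini-Hochberg wrapper kept in one place so every module corrects the
# same way.
bh_adjust <- function(p) p.adjust(p, method = "BH")

`%||%` <- function(a, b) if (is.null(a)) b else a
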