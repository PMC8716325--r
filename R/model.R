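#' Configure the joint classification-segmentation architecture
#'
#' One configuration drives both the miniature CPU-trainable variant and the
#' scan-scale variant of the model: a residual convolutional encoder that
#' halves resolution once per stage, a patch-level classification head and a
#' coarse region-proposal (RPN) head on the deepest feature map, and a
#' skip-connected transposed-convolution decoder that upsamples the deepest
#' map back to input resolution as a per-pixel lesion probability image.
#'
#' @param input_size Side length of the square input patch in pixels.
#' @param stem_channels Channels produced by the initial full-resolution
#'   convolution (also the finest skip feature fed to the decoder).
#' @param encoder_stages List of `c(blocks, channels)` pairs, one per
#'   downsampling stage: each stage opens with a stride-2 convolution and is
#'   followed by `blocks` residual blocks at `channels` width.
#' @param deepest_grid Side length of the deepest feature map; must equal
#'   `input_size / 2^length(encoder_stages)`.
#' @param decoder_blocks Number of x2 upsampling blocks; must equal
#'   `log2(input_size / deepest_grid)`.
#' @param rpn_grid_channels Channels of the RPN score map (2: a per-cell
#'   background/lesion softmax pair).
#' @param skip_connections Concatenate matching-resolution encoder features
#'   into each decoder block (`FALSE` gives the skip-free ablation).
#' @param heads Character subset of `c("classify", "rpn", "segment")`.
#' @param rpn_positive_fraction Fraction of annotated pixels a grid cell must
#'   contain to count as a positive RPN target (see [rpn_targets()]).
#' @return An object of class `seg_model_config`.
#' @examples
#' cfg <- seg_model_config()            # 64-px miniature variant
#' # scan-scale arithmetic: 256 px over 5 downsamplings gives an 8x8 deepest
#' # grid and forces exactly 5 decoder blocks
#' big <- seg_model_config(input_size = 256, stem_channels = 64,
#'   encoder_stages = list(c(3, 256), c(4, 512), c(6, 1024), c(3, 2048),
#'                         c(1, 2048)),
#'   deepest_grid = 8, decoder_blocks = 5)
#' @export
seg_model_config <- function(input_size = 64,
                             stem_channels = 6,
                             encoder_stages = list(c(1, 12), c(1, 16),
                                                   c(1, 24), c(1, 32)),
                             deepest_grid = input_size / 2^length(encoder_stages),
                             decoder_blocks = log2(input_size / deepest_grid),
                             rpn_grid_channels = 2,
                             skip_connections = TRUE,
                             heads = c("classify", "rpn", "segment"),
                             rpn_positive_fraction = 0.1) {
  stages <- lapply(encoder_stages, function(s) {
    s <- as.integer(s)
    if (length(s) != 2 || any(s < 1)) {
      stop("each encoder stage must be c(blocks >= 1, channels >= 1)")
    }
    list(blocks = s[1], channels = s[2])
  })
  n_down <- length(stages)
  if (input_size %% 2^n_down != 0 ||
      input_size / 2^n_down != deepest_grid) {
    stop("configuration error: input_size after ", n_down,
         " halvings is ", input_size / 2^n_down,
         " but deepest_grid is ", deepest_grid)
  }
  if (decoder_blocks != log2(input_size / deepest_grid)) {
    stop("configuration error: decoder_blocks must be ",
         "log2(input_size / deepest_grid) = ",
         log2(input_size / deepest_grid), ", got ", decoder_blocks)
  }
  heads <- match.arg(heads, c("classify", "rpn", "segment"),
                     several.ok = TRUE)
  structure(list(input_size = as.integer(input_size),
                 stem_channels = as.integer(stem_channels),
                 encoder_stages = stages,
                 deepest_grid = as.integer(deepest_grid),
                 deepest_channels = stages[[n_down]]$channels,
                 decoder_blocks = as.integer(decoder_blocks),
                 rpn_grid_channels = as.integer(rpn_grid_channels),
                 skip_connections = isTRUE(skip_connections),
                 heads = heads,
                 rpn_positive_fraction = rpn_positive_fraction),
            class = "seg_model_config")
}

# Channel widths of the decoder skip levels, finest first:
# level l = 1..S holds the feature map at resolution input_size / 2^(l-1).
skip_channels <- function(cfg) {
  s <- length(cfg$encoder_stages)
  c(cfg$stem_channels,
    vapply(cfg$encoder_stages[seq_len(s - 1)], `[[`, 0L, "channels"))
}

#' Instantiate model weights for a configuration
#'
#' Allocates He-initialized weights for every layer implied by the
#' configuration. Parameters are grouped as `encoder`, `classify_head`,
#' `rpn_head` and `decoder` so that groups can be frozen or transferred
#' independently. The final mask convolution starts with a negative bias, so
#' an untrained model predicts background; screening data is dominated by
#' healthy tissue and this keeps early training stable.
#'
#' @param cfg A [seg_model_config()].
#' @param seed Optional integer; when given, initialization uses a private
#'   RNG stream and the build is reproducible.
#' @return An object of class `seg_model` with elements `cfg` and `params`.
#' @export
build_model <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "seg_model_config"))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(seed)
  }
  sc <- cfg$stem_channels
  enc <- list(stem = init_conv(3, 1, sc, bn = TRUE))
  cin <- sc
  for (s in seq_along(cfg$encoder_stages)) {
    st <- cfg$encoder_stages[[s]]
    stage <- list(down = init_conv(3, cin, st$channels, bn = TRUE))
    for (j in seq_len(st$blocks)) {
      stage[[paste0("block", j)]] <- list(
        conv1 = init_conv(3, st$channels, st$channels, bn = TRUE),
        conv2 = init_conv(3, st$channels, st$channels, bn = TRUE))
    }
    enc[[paste0("stage", s)]] <- stage
    cin <- st$channels
  }
  params <- list(encoder = enc)
  cdeep <- cfg$deepest_channels
  if ("classify" %in% cfg$heads) {
    params$classify_head <- init_dense(cdeep, 1, gain = 1)
  }
  if ("rpn" %in% cfg$heads) {
    params$rpn_head <- init_conv(1, cdeep, cfg$rpn_grid_channels, gain = 1)
  }
  if ("segment" %in% cfg$heads) {
    skc <- rev(skip_channels(cfg))   # coarsest first, matching block order
    dec <- list()
    cin <- cdeep
    for (d in seq_len(cfg$decoder_blocks)) {
      cs <- skc[d]
      conv_in <- if (cfg$skip_connections) 2L * cs else cs
      dec[[paste0("block", d)]] <- list(
        up = init_conv(2, cin, cs, bn = TRUE),
        conv = init_conv(3, conv_in, cs, bn = TRUE))
      cin <- cs
    }
    final <- init_conv(1, cin, 1, gain = 1)
    final$b[] <- -2  # background prior
    dec$final <- final
    params$decoder <- dec
  }
  structure(list(cfg = cfg, params = params,
                 bn = new.env(parent = emptyenv())),
            class = "seg_model")
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Forward pass over a batch x of dims (H, W, 1, N). Returns the model
# outputs (y, rpn, M) and, when want_cache, every tensor backward needs.
# `train_groups` lists the components ("encoder", "decoder") whose batch
# norms run in training mode (batch statistics + buffer updates); all
# others use their running statistics, so a frozen group is bit-stable.
forward_pass <- function(model, x, heads = model$cfg$heads,
                         want_cache = FALSE, train_groups = character()) {
  cfg <- model$cfg
  p <- model$params
  bn <- model$bn
  stopifnot(length(dim(x)) == 4, dim(x)[1] == cfg$input_size)
  tr_enc <- "encoder" %in% train_groups
  tr_dec <- "decoder" %in% train_groups
  n_stage <- length(cfg$encoder_stages)
  skips <- vector("list", n_stage + 1)
  enc_cache <- list(stages = vector("list", n_stage))
  r <- cbr_fw(x, p$encoder$stem, bn, "enc/stem", tr_enc)
  a <- r$out
  enc_cache$stem <- r$cache
  skips[[1]] <- a
  for (s in seq_len(n_stage)) {
    st <- cfg$encoder_stages[[s]]
    stage <- p$encoder[[paste0("stage", s)]]
    r <- cbr_fw(a, stage$down, bn, paste0("enc/s", s, "/down"), tr_enc,
                stride = 2)
    a <- r$out
    sc <- list(down = r$cache, blocks = vector("list", st$blocks))
    for (j in seq_len(st$blocks)) {
      blk <- stage[[paste0("block", j)]]
      key <- paste0("enc/s", s, "/b", j)
      r1 <- cbr_fw(a, blk$conv1, bn, paste0(key, "/c1"), tr_enc)
      r2 <- cbr_fw(r1$out, blk$conv2, bn, paste0(key, "/c2"), tr_enc,
                   act = FALSE)
      pre <- a + r2$out
      sc$blocks[[j]] <- list(c1 = r1$cache, c2 = r2$cache,
                             premask = (pre > 0))
      a <- relu(pre)
    }
    enc_cache$stages[[s]] <- sc
    skips[[s + 1]] <- a
  }
  deepest <- a
  dd <- dim(deepest)
  out <- list()
  if ("classify" %in% heads && !is.null(p$classify_head)) {
    gap <- matrix(colMeans(matrix(deepest, dd[1] * dd[2], dd[3] * dd[4])),
                  dd[3], dd[4])
    ylogit <- drop(crossprod(gap, p$classify_head$W)) + p$classify_head$b
    out$ylogit <- ylogit
    out$y <- sigmoid(ylogit)
    if (want_cache) out$gap <- gap
  }
  if ("rpn" %in% heads && !is.null(p$rpn_head)) {
    rl <- conv_fw(deepest, p$rpn_head, stride = 1, pad = 0)
    out$rpn_logits <- rl
    out$rpn <- softmax_channels(rl)
  }
  dec_cache <- NULL
  if ("segment" %in% heads && !is.null(p$decoder)) {
    nb <- cfg$decoder_blocks
    d <- deepest
    blocks <- vector("list", nb)
    for (b in seq_len(nb)) {
      blk <- p$decoder[[paste0("block", b)]]
      ru <- tbr_fw(d, blk$up, bn, paste0("dec/b", b, "/up"), tr_dec)
      cat_ <- if (cfg$skip_connections) {
        cat_channels(ru$out, skips[[nb + 1 - b]])
      } else ru$out
      rc <- cbr_fw(cat_, blk$conv, bn, paste0("dec/b", b, "/conv"), tr_dec)
      blocks[[b]] <- list(up = ru$cache, conv = rc$cache)
      d <- rc$out
    }
    mlogit <- conv_fw(d, p$decoder$final, stride = 1, pad = 0)
    out$Mlogit <- mlogit
    out$M <- sigmoid(mlogit)
    if (want_cache) dec_cache <- list(blocks = blocks, out = d)
  }
  if (want_cache) {
    out$cache <- list(x = x, skips = skips, enc = enc_cache,
                      deepest = deepest, dec = dec_cache)
  }
  out
}

# Numerically stable per-cell softmax over the 2-channel axis.
softmax_channels <- function(rl) {
  m <- pmax(rl[, , 1, , drop = FALSE], rl[, , 2, , drop = FALSE])
  e1 <- exp(rl[, , 1, , drop = FALSE] - m)
  e2 <- exp(rl[, , 2, , drop = FALSE] - m)
  z <- e1 + e2
  out <- rl
  out[, , 1, ] <- e1 / z
  out[, , 2, ] <- e2 / z
  out
}

# Backward pass. g holds any of gMlogit (H,W,1,N), gylogit (length N),
# grpn_logits (g,g,2,N) — gradients of the scalar loss w.r.t. the
# pre-squashing outputs. `groups` names the parameter groups that need
# gradients; omitting "encoder" skips the encoder sweep entirely (used
# during the frozen warm-up phase).
backward_pass <- function(model, fw, g, groups = names(model$params)) {
  cfg <- model$cfg
  p <- model$params
  cache <- fw$cache
  grads <- list()
  n_stage <- length(cfg$encoder_stages)
  gskips <- vector("list", n_stage + 1)
  gdeepest <- zero_arr(cache$deepest)

  if (!is.null(g$gMlogit) && !is.null(p$decoder) &&
      "decoder" %in% groups) {
    dec <- cache$dec
    nb <- cfg$decoder_blocks
    gdec <- list()
    bw <- conv_bw(dec$out, p$decoder$final, g$gMlogit, stride = 1, pad = 0)
    gdec$final <- list(W = bw$gw, b = bw$gb)
    gh <- bw$gx
    for (b in rev(seq_len(nb))) {
      blk <- p$decoder[[paste0("block", b)]]
      bc <- cbr_bw(gh, blk$conv, dec$blocks[[b]]$conv)
      gcat <- bc$gx
      cs <- dim(blk$up$W)[4]
      if (cfg$skip_connections) {
        gu <- gcat[, , seq_len(cs), , drop = FALSE]
        gsk <- gcat[, , cs + seq_len(dim(gcat)[3] - cs), , drop = FALSE]
        lvl <- nb + 1 - b
        gskips[[lvl]] <- if (is.null(gskips[[lvl]])) gsk
                         else gskips[[lvl]] + gsk
      } else {
        gu <- gcat
      }
      bu <- tbr_bw(gu, blk$up, dec$blocks[[b]]$up)
      gdec[[paste0("block", b)]] <- list(up = bu$grads, conv = bc$grads)
      gh <- bu$gx
    }
    gdeepest <- gdeepest + gh
    grads$decoder <- gdec
  }

  if (!is.null(g$gylogit) && !is.null(p$classify_head)) {
    dd <- dim(cache$deepest)
    if ("classify_head" %in% groups) {
      grads$classify_head <- list(
        W = fw$gap %*% matrix(g$gylogit, ncol = 1),
        b = sum(g$gylogit))
    }
    # d gap[c, n] / d deepest[i, j, c, n] = 1 / grid^2
    ggap <- p$classify_head$W %*% matrix(g$gylogit, nrow = 1)  # (C, N)
    gdeepest <- gdeepest +
      aperm(array(ggap / (dd[1] * dd[2]), c(dd[3], dd[4], dd[1], dd[2])),
            c(3, 4, 1, 2))
  }

  if (!is.null(g$grpn_logits) && !is.null(p$rpn_head)) {
    bw <- conv_bw(cache$deepest, p$rpn_head, g$grpn_logits,
                  stride = 1, pad = 0)
    if ("rpn_head" %in% groups) grads$rpn_head <- list(W = bw$gw, b = bw$gb)
    gdeepest <- gdeepest + bw$gx
  }

  if ("encoder" %in% groups) {
    genc <- list()
    ga <- gdeepest    # grad w.r.t. skips[[n_stage + 1]]
    for (s in rev(seq_len(n_stage))) {
      st <- cfg$encoder_stages[[s]]
      stage <- p$encoder[[paste0("stage", s)]]
      sc <- cache$enc$stages[[s]]
      gstage <- list()
      for (j in rev(seq_len(st$blocks))) {
        blk <- stage[[paste0("block", j)]]
        bc <- sc$blocks[[j]]
        gpre <- ga * bc$premask
        b2 <- cbr_bw(gpre, blk$conv2, bc$c2)
        b1 <- cbr_bw(b2$gx, blk$conv1, bc$c1)
        gstage[[paste0("block", j)]] <- list(conv1 = b1$grads,
                                             conv2 = b2$grads)
        ga <- gpre + b1$gx           # residual shortcut + conv path
      }
      bd <- cbr_bw(ga, stage$down, sc$down)
      gstage$down <- bd$grads
      genc[[paste0("stage", s)]] <- gstage
      ga <- bd$gx
      if (!is.null(gskips[[s]])) ga <- ga + gskips[[s]]
    }
    bs <- cbr_bw(ga, p$encoder$stem, cache$enc$stem)
    genc$stem <- bs$grads
    grads$encoder <- genc
  }
  grads
}

zero_arr <- function(a) array(0, dim(a))

#' Transfer pretrained encoder and head weights into a full model
#'
#' Copies the encoder (and any head present in both models) from a
#' pretrained classification/region-proposal model into a freshly built full
#' model, leaving the decoder at its fresh initialization. This is the
#' weight-transfer step between region-proposal pretraining and staged
#' fine-tuning of the segmentation decoder.
#'
#' @param source A pretrained `seg_model` (typically built with
#'   `heads = c("classify", "rpn")`).
#' @param target A full `seg_model` whose encoder configuration matches
#'   `source` exactly.
#' @return `target` with copied weights; attribute `"transfer_report"` is a
#'   data frame listing each parameter group as `"copied"` or `"fresh"`.
#' @export
transfer_weights <- function(source, target) {
  stopifnot(inherits(source, "seg_model"), inherits(target, "seg_model"))
  check_same_shapes(source$params$encoder, target$params$encoder, "encoder")
  report <- data.frame(group = character(), status = character())
  target$params$encoder <- source$params$encoder
  # carry over the encoder's batch-norm running statistics as well
  src_bn <- bn_snapshot(source)
  for (k in grep("^enc/", names(src_bn), value = TRUE)) {
    target$bn[[k]] <- src_bn[[k]]
  }
  report <- rbind(report, data.frame(group = "encoder", status = "copied"))
  for (head in c("classify_head", "rpn_head")) {
    if (!is.null(source$params[[head]]) && !is.null(target$params[[head]])) {
      check_same_shapes(source$params[[head]], target$params[[head]], head)
      target$params[[head]] <- source$params[[head]]
      report <- rbind(report, data.frame(group = head, status = "copied"))
    } else if (!is.null(target$params[[head]])) {
      report <- rbind(report, data.frame(group = head, status = "fresh"))
    }
  }
  if (!is.null(target$params$decoder)) {
    report <- rbind(report, data.frame(group = "decoder", status = "fresh"))
  }
  attr(target, "transfer_report") <- report
  target
}

check_same_shapes <- function(a, b, path) {
  if (is.list(a) != is.list(b)) {
    stop("weight transfer mismatch at group '", path, "'")
  }
  if (is.list(a)) {
    if (!identical(sort(names(a)), sort(names(b)))) {
      stop("weight transfer mismatch at group '", path, "'")
    }
    for (nm in names(a)) {
      check_same_shapes(a[[nm]], b[[nm]], paste(path, nm, sep = "$"))
    }
  } else if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
    stop("weight transfer mismatch at group '", path, "'")
  }
  invisible(TRUE)
}

#' Coarse region-proposal targets from an annotation mask
#'
#' Divides the annotation mask into a `grid` x `grid` lattice of equal square
#' cells and marks a cell positive when the fraction of annotated pixels in
#' it reaches `positive_fraction`. These per-cell objectness targets drive
#' the RPN head during encoder pretraining.
#'
#' @param annotation Binary matrix whose side is divisible by `grid`.
#' @param grid Number of cells per side (the deepest feature-map size).
#' @param positive_fraction Minimum annotated fraction for a positive cell.
#' @return A `grid` x `grid` binary matrix.
#' @examples
#' ann <- matrix(0, 64, 64); ann[1:16, 1:16] <- 1
#' rpn_targets(ann, grid = 4)   # exactly one positive cell
#' @export
rpn_targets <- function(annotation, grid, positive_fraction = 0.1) {
  annotation <- as.matrix(annotation)
  n <- nrow(annotation)
  if (n != ncol(annotation) || n %% grid != 0) {
    stop("annotation side must be square and divisible by grid")
  }
  cell <- n %/% grid
  # per-cell positive fraction via a (cell, grid, cell, grid) reshape
  frac <- apply(array(annotation > 0, c(cell, grid, cell, grid)),
                c(2, 4), mean)
  matrix(as.integer(frac >= positive_fraction), grid, grid)
}
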