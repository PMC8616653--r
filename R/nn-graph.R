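# Static computational-graph engine.
#
# A model is a named list of nodes in topological order. Each node is an
# environment (so weights, optimizer state and forward caches mutate in
# place) holding: op, inputs (names of upstream nodes, ".input" for the
# image), params (trainable arrays), args (structural constants), stats
# (batch-norm running moments), cache (forward activations needed by the
# backward pass), grads (parameter gradients of the last backward pass) and
# opt (Adam moments). Activations are dense (H, W, C, N) double arrays.

new_node <- function(op, inputs = character(), params = list(),
                     args = list(), stats = NULL) {
  e <- new.env(parent = emptyenv())
  e$op <- op
  e$inputs <- inputs
  e$params <- params
  e$args <- args
  e$stats <- stats
  e$cache <- NULL
  e$grads <- NULL
  e$opt <- list()
  e
}

graph_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  add <- function(name, op, inputs = character(), params = list(),
                  args = list(), stats = NULL) {
    if (name %in% names(env$nodes)) stop("duplicate node name: ", name)
    unknown <- setdiff(inputs, c(".input", names(env$nodes)))
    if (length(unknown)) {
      stop("node '", name, "' refers to unknown input(s): ",
           paste(unknown, collapse = ", "))
    }
    env$nodes[[name]] <- new_node(op, inputs, params, args, stats)
    name
  }
  list(add = add, nodes = function() env$nodes)
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

finish_model <- function(config, gb, output) {
  nodes <- gb$nodes()
  structure(
    list(config = config, nodes = nodes, order = names(nodes), output = output),
    class = "fissure_model"
  )
}

# ---- op dispatch -----------------------------------------------------------

op_forward <- function(node, ins, training) {
  switch(node$op,
    conv = {
      x <- ins[[1]]
      node$cache <- list(x = x)
      conv2d_fwd_cpp(x, node$params$w, node$params$b,
                     node$args$padh, node$args$padw)
    },
    dwconv = {
      x <- ins[[1]]
      node$cache <- list(x = x)
      dwconv_fwd_cpp(x, node$params$w, node$params$b,
                     node$args$padh, node$args$padw)
    },
    bn = bn_forward(node, ins[[1]], training),
    relu = {
      x <- ins[[1]]
      m <- x > 0
      node$cache <- list(m = m)
      x * m
    },
    pool = {
      r <- maxpool_fwd_cpp(ins[[1]], node$args$k, node$args$stride,
                           node$args$pad)
      node$cache <- list(idx = r$idx, xdim = dim(ins[[1]]))
      r$y
    },
    upconv = {
      x <- ins[[1]]
      node$cache <- list(x = x)
      upconv2_fwd_cpp(x, node$params$w, node$params$b)
    },
    upsample2 = {
      d <- dim(ins[[1]])
      node$cache <- list(H = d[1], W = d[2])
      resize_bilinear_cpp(ins[[1]], 2L * d[1], 2L * d[2])
    },
    add = Reduce(`+`, ins),
    concat = {
      dims <- lapply(ins, dim)
      cs <- vapply(dims, function(d) d[3], numeric(1))
      H <- dims[[1]][1]; W <- dims[[1]][2]; N <- dims[[1]][4]
      y <- array(0, c(H, W, sum(cs), N))
      off <- 0
      for (k in seq_along(ins)) {
        y[, , (off + 1):(off + cs[k]), ] <- ins[[k]]
        off <- off + cs[k]
      }
      node$cache <- list(cs = cs)
      y
    },
    gap = {
      x <- ins[[1]]
      d <- dim(x)
      dim(x) <- c(d[1] * d[2], d[3], d[4])
      node$cache <- list(H = d[1], W = d[2])
      array(colMeans(x), c(1, 1, d[3], d[4]))
    },
    sigmoid = {
      y <- 1 / (1 + exp(-ins[[1]]))
      node$cache <- list(y = y)
      y
    },
    scale = {
      x <- ins[[1]]; g <- ins[[2]]
      node$cache <- list(x = x, g = g)
      x * expand_cn(g, dim(x)[1], dim(x)[2])
    },
    stop("unknown op: ", node$op)
  )
}

op_backward <- function(node, dy) {
  switch(node$op,
    conv = {
      r <- conv2d_bwd_cpp(node$cache$x, node$params$w, dy,
                          node$args$padh, node$args$padw,
                          !is.null(node$params$b))
      node$grads <- list(w = r$dw,
                         b = if (!is.null(node$params$b)) r$db)
      list(r$dx)
    },
    dwconv = {
      r <- dwconv_bwd_cpp(node$cache$x, node$params$w, dy,
                          node$args$padh, node$args$padw,
                          !is.null(node$params$b))
      node$grads <- list(w = r$dw,
                         b = if (!is.null(node$params$b)) r$db)
      list(r$dx)
    },
    bn = bn_backward(node, dy),
    relu = list(dy * node$cache$m),
    pool = list(maxpool_bwd_cpp(node$cache$idx, dy, node$cache$xdim)),
    upconv = {
      r <- upconv2_bwd_cpp(node$cache$x, node$params$w, dy,
                           !is.null(node$params$b))
      node$grads <- list(w = r$dw,
                         b = if (!is.null(node$params$b)) r$db)
      list(r$dx)
    },
    upsample2 = list(resize_bilinear_bwd_cpp(dy, node$cache$H, node$cache$W)),
    add = rep(list(dy), length(node$inputs)),
    concat = {
      cs <- node$cache$cs
      out <- vector("list", length(cs))
      off <- 0
      for (k in seq_along(cs)) {
        out[[k]] <- dy[, , (off + 1):(off + cs[k]), , drop = FALSE]
        off <- off + cs[k]
      }
      out
    },
    gap = {
      H <- node$cache$H; W <- node$cache$W
      list(expand_cn(dy / (H * W), H, W))
    },
    sigmoid = list(dy * node$cache$y * (1 - node$cache$y)),
    scale = {
      x <- node$cache$x; g <- node$cache$g
      d <- dim(x)
      dx <- dy * expand_cn(g, d[1], d[2])
      t0 <- dy * x
      dim(t0) <- c(d[1] * d[2], d[3], d[4])
      dg <- array(colSums(t0), c(1, 1, d[3], d[4]))
      list(dx, dg)
    },
    stop("unknown op: ", node$op)
  )
}

# ---- batch normalization ---------------------------------------------------

bn_forward <- function(node, x, training) {
  d <- dim(x)
  HW <- d[1] * d[2]
  g <- node$params$gamma
  b <- node$params$beta
  eps <- node$args$eps
  if (training) {
    mu <- chan_mean(x)
    s2 <- chan_mean(x * x) - mu^2
    s2 <- pmax(s2, 0)
    invstd <- 1 / sqrt(s2 + eps)
    xhat <- (x - rep(mu, each = HW)) * rep(invstd, each = HW)
    node$cache <- list(xhat = xhat, invstd = invstd, M = HW * d[4])
    mom <- node$args$momentum
    node$stats$mean <- mom * node$stats$mean + (1 - mom) * mu
    node$stats$var <- mom * node$stats$var + (1 - mom) * s2
    xhat * rep(g, each = HW) + rep(b, each = HW)
  } else {
    invstd <- 1 / sqrt(node$stats$var + eps)
    (x - rep(node$stats$mean, each = HW)) * rep(invstd * g, each = HW) +
      rep(b, each = HW)
  }
}

bn_backward <- function(node, dy) {
  xhat <- node$cache$xhat
  invstd <- node$cache$invstd
  M <- node$cache$M
  d <- dim(xhat)
  HW <- d[1] * d[2]
  g <- node$params$gamma
  dxhat <- dy * rep(g, each = HW)
  s1 <- chan_sum(dxhat)
  s2 <- chan_sum(dxhat * xhat)
  node$grads <- list(gamma = chan_sum(dy * xhat), beta = chan_sum(dy))
  dx <- rep(invstd, each = HW) *
    (dxhat - rep(s1 / M, each = HW) - xhat * rep(s2 / M, each = HW))
  list(dx)
}

# ---- execution -------------------------------------------------------------

nn_forward <- function(model, x, training = FALSE) {
  acts <- new.env(parent = emptyenv())
  assign(".input", x, envir = acts)
  for (nm in model$order) {
    node <- model$nodes[[nm]]
    ins <- lapply(node$inputs, function(i) get(i, envir = acts))
    assign(nm, op_forward(node, ins, training), envir = acts)
  }
  list(out = get(model$output, envir = acts), acts = acts)
}

nn_backward <- function(model, dout) {
  grads <- new.env(parent = emptyenv())
  assign(model$output, dout, envir = grads)
  for (nm in rev(model$order)) {
    if (!exists(nm, envir = grads, inherits = FALSE)) next
    node <- model$nodes[[nm]]
    dins <- op_backward(node, get(nm, envir = grads))
    for (k in seq_along(node$inputs)) {
      inm <- node$inputs[k]
      if (inm == ".input") next
      if (exists(inm, envir = grads, inherits = FALSE)) {
        assign(inm, get(inm, envir = grads) + dins[[k]], envir = grads)
      } else {
        assign(inm, dins[[k]], envir = grads)
      }
    }
  }
  invisible(grads)
}

#' Run a model forward on an image or feature grid
#'
#' Executes the node graph in topological order. Accepts a single `(H, W, C)`
#' grid or a batch `(H, W, C, N)`; a single grid comes back as `(H, W, C)`.
#' In training mode batch-norm layers use (and update) batch statistics; in
#' inference mode they use the stored running moments, so repeated calls on
#' the same input are bit-identical.
#'
#' @param model a `fissure_model` (see [build_improved_unet()] or the
#'   `new_*_block()` constructors).
#' @param x input array, `(H, W, C)` or `(H, W, C, N)`.
#' @param training logical; use batch statistics and keep backward caches.
#' @return the output grid of the model's final node.
#' @export
model_forward <- function(model, x, training = FALSE) {
  single <- length(dim(x)) == 3
  x4 <- as4d(x)
  if (isTRUE(model$config$check_input)) {
    d <- dim(x4)
    if (d[1] %% 32 != 0 || d[2] %% 32 != 0) {
      stop("input spatial dimensions must be divisible by 32, got ",
           d[1], "x", d[2])
    }
    if (d[3] != model$config$in_channels) {
      stop("input has ", d[3], " channels; model expects ",
           model$config$in_channels)
    }
  }
  out <- nn_forward(model, x4, training)$out
  if (single && dim(out)[4] == 1) {
    d <- dim(out)
    dim(out) <- d[1:3]
  }
  out
}

# ---- weights, parameter counting ------------------------------------------

#' Extract all weights (and batch-norm running moments) of a model
#'
#' @param model a `fissure_model`.
#' @return a named list, one entry per parameterized node, with the node's
#'   trainable arrays plus any running statistics under `.stats`.
#' @export
model_weights <- function(model) {
  out <- list()
  for (nm in model$order) {
    node <- model$nodes[[nm]]
    if (!length(node$params) && is.null(node$stats)) next
    entry <- node$params
    if (!is.null(node$stats)) entry$.stats <- node$stats
    out[[nm]] <- entry
  }
  out
}

#' Set model weights from a list produced by [model_weights()]
#'
#' @param model a `fissure_model`.
#' @param weights named list of per-node parameter arrays.
#' @return the model, invisibly (nodes are modified in place).
#' @export
set_model_weights <- function(model, weights) {
  for (nm in names(weights)) {
    node <- model$nodes[[nm]]
    if (is.null(node)) stop("model has no node named '", nm, "'")
    entry <- weights[[nm]]
    st <- entry$.stats
    entry$.stats <- NULL
    for (pn in names(entry)) {
      if (is.null(node$params[[pn]])) next
      stopifnot(length(node$params[[pn]]) == length(entry[[pn]]))
      node$params[[pn]] <- entry[[pn]]
    }
    if (!is.null(st)) node$stats <- st
  }
  invisible(model)
}

#' Count trainable parameters of a model
#'
#' Counts every element of every trainable array (convolution weights and
#' biases, batch-norm gains and offsets). Running statistics are not counted.
#'
#' @param model a `fissure_model`.
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  total <- 0
  for (nm in model$order) {
    for (p in model$nodes[[nm]]$params) total <- total + length(p)
  }
  as.integer(total)
}

#' Structural layer table of a model
#'
#' One row per node: its operation, structural detail and the exact number
#' of trainable parameters, computable without running the model. The column
#' sum equals [count_params()].
#'
#' @param model a `fissure_model`.
#' @return a data.frame with columns `name`, `op`, `detail`, `n_params`.
#' @export
layer_specs <- function(model) {
  rows <- lapply(model$order, function(nm) {
    node <- model$nodes[[nm]]
    np <- sum(vapply(node$params, length, numeric(1)))
    detail <- switch(node$op,
      conv = {
        d <- dim(node$params$w)
        sprintf("%dx%d %d->%d%s", d[1], d[2], d[3], d[4],
                if (is.null(node$params$b)) " (no bias)" else "")
      },
      dwconv = {
        d <- dim(node$params$w)
        sprintf("%dx%d depthwise on %d", d[1], d[2], d[3])
      },
      upconv = {
        d <- dim(node$params$w)
        sprintf("2x2 stride-2 transposed %d->%d", d[3], d[4])
      },
      bn = sprintf("%d channels", length(node$params$gamma)),
      pool = sprintf("%dx%d stride %d", node$args$k, node$args$k,
                     node$args$stride),
      ""
    )
    data.frame(name = nm, op = node$op, detail = detail, n_params = np,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.fissure_model <- function(x, ...) {
  cat("<fissure_model> ", length(x$order), " nodes, ",
      format(count_params(x), big.mark = ","), " parameters\n", sep = "")
  cfg <- x$config
  if (!is.null(cfg$encoder)) {
    cat("  encoder: ", cfg$encoder,
        if (isTRUE(cfg$use_gcn)) {
          sprintf(" + GCN(k=%d, %s)", cfg$gcn_kernel_size, cfg$gcn_variant)
        } else "",
        if (isTRUE(cfg$use_br)) " + BR" else "",
        ", ", cfg$num_classes, " classes\n", sep = "")
  }
  invisible(x)
}

# ---- Adam ------------------------------------------------------------------

adam_step <- function(model, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      t = 1) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in model$order) {
    node <- model$nodes[[nm]]
    if (!length(node$params)) next
    for (pn in names(node$params)) {
      p <- node$params[[pn]]
      if (is.null(p)) next
      gr <- node$grads[[pn]]
      if (is.null(gr)) next
      o <- node$opt[[pn]]
      if (is.null(o)) o <- list(m = p * 0, v = p * 0)
      o$m <- beta1 * o$m + (1 - beta1) * gr
      o$v <- beta2 * o$v + (1 - beta2) * gr * gr
      node$opt[[pn]] <- o
      node$params[[pn]] <- p - lr * (o$m / bc1) / (sqrt(o$v / bc2) + eps)
    }
  }
  invisible(model)
}
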