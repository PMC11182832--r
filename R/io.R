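#' Read a network from extended Newick or JSON
#'
#' Extended Newick uses `#H<k>` hybrid tags: the reticulation vertex occurs
#' twice, once with its subtree.  The rooted reading is converted to a
#' semi-directed network by suppressing the root and keeping only the
#' reticulation edges directed.  The JSON dialect is
#' `{"leaves": {label: vertex, ...}, "tree_edges": [[u, v], ...],
#' "reticulations": [{"head": v, "tails": [a, b]}]}`.
#'
#' @param x path to a file, or the text itself.
#' @param format `"enewick"` or `"json"`; guessed from content when missing.
#' @return a validated `sdnet`.
#' @export
parse_network <- function(x, format = NULL) {
  text <- if (file.exists(x)) paste(readLines(x, warn = FALSE),
                                    collapse = "\n") else x
  if (is.null(format))
    format <- if (grepl("^\\s*[{\\[]", text)) "json" else "enewick"
  switch(format,
         json = parse_network_json(text),
         enewick = parse_enewick(text),
         stop("unknown format: ", format))
}

parse_network_json <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  lv <- obj$leaves
  leaves <- if (is.null(names(lv)))
    stats::setNames(unlist(lv), unlist(lv)) else
    stats::setNames(unlist(lv), names(lv))
  te <- obj$tree_edges %||% list()
  ret <- obj$reticulations %||% list()
  eid <- 0L
  rows <- list()
  for (e in te) {
    eid <- eid + 1L
    rows[[eid]] <- data.frame(id = paste0("e", eid), tail = e[[1L]],
                              head = e[[2L]], type = "tree")
  }
  for (r in ret) for (tl in r$tails) {
    eid <- eid + 1L
    rows[[eid]] <- data.frame(id = paste0("e", eid), tail = tl,
                              head = r$head, type = "ret")
  }
  ed <- do.call(rbind, rows)
  vs <- unique(c(ed$tail, ed$head))
  sdnet(vs, ed, leaves)
}

#' Write a network to the JSON dialect
#'
#' @param net an `sdnet`.
#' @param path optional output file; otherwise the JSON text is returned.
#' @return the JSON text, invisibly when written to a file.
#' @export
write_network_json <- function(net, path = NULL) {
  e <- net$edges
  rv <- ret_vertices(net)
  obj <- list(
    leaves = as.list(stats::setNames(unname(net$leaves), names(net$leaves))),
    tree_edges = lapply(which(e$type == "tree"),
                        function(i) c(e$tail[i], e$head[i])),
    reticulations = lapply(rv, function(v)
      list(head = v, tails = e$tail[e$type == "ret" & e$head == v])))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

# --- extended Newick -------------------------------------------------------

parse_enewick <- function(text) {
  s <- gsub("\\s", "", text)
  s <- sub(";$", "", s)
  pos <- 1L
  nvert <- 0L
  rows <- list()
  leaves <- character(0)
  hybrids <- new.env(parent = emptyenv())
  peek <- function() if (pos > nchar(s)) "" else substr(s, pos, pos)
  advance <- function() pos <<- pos + 1L
  read_name <- function() {
    start <- pos
    while (peek() != "" && !(peek() %in% c("(", ")", ",", ":", ";")))
      advance()
    substr(s, start, pos - 1L)
  }
  new_vertex <- function() { nvert <<- nvert + 1L; paste0("n", nvert) }
  add_edge <- function(tail, head, type) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = paste0("e", length(rows) + 1L), tail = tail, head = head,
      type = type)
  }
  # returns vertex id of the parsed clade
  parse_clade <- function() {
    children <- list()
    if (peek() == "(") {
      advance()
      repeat {
        children[[length(children) + 1L]] <- parse_clade()
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        stop("parse error at position ", pos, ": expected ',' or ')'")
      }
    }
    name <- read_name()
    if (peek() == ":") {  # branch lengths are accepted and ignored
      advance(); read_name()
    }
    hybrid <- grepl("#H", name, fixed = TRUE)
    if (hybrid) {
      tag <- sub(".*#H", "", name)
      if (is.null(hybrids[[tag]])) hybrids[[tag]] <- new_vertex()
      v <- hybrids[[tag]]
      attr(v, "hybrid") <- TRUE
    } else {
      v <- new_vertex()
      if (length(children) == 0L) {
        if (name == "") stop("parse error: unnamed leaf at position ", pos)
        leaves[[name]] <<- v
      }
    }
    for (ch in children)
      add_edge(v, ch, if (isTRUE(attr(ch, "child_hybrid"))) "ret" else "tree")
    out <- as.character(v)
    attr(out, "child_hybrid") <- hybrid
    out
  }
  root <- parse_clade()
  if (pos <= nchar(s)) stop("parse error: trailing text at position ", pos)
  ed <- do.call(rbind, rows)
  vs <- unique(c(ed$tail, ed$head))
  # suppress the root and any other degree-2 vertex introduced by rooting
  repeat {
    deg <- table(c(ed$tail, ed$head))
    two <- names(deg)[deg == 2L]
    two <- setdiff(two, c(unname(unlist(as.list(leaves))),
                          unique(ed$head[ed$type == "ret"])))
    if (length(two) == 0L) break
    v <- two[1L]
    inc <- which(ed$tail == v | ed$head == v)
    e1 <- ed[inc[1L], ]; e2 <- ed[inc[2L], ]
    if (any(c(e1$type, e2$type) == "ret")) {
      r <- if (e1$type == "ret") e1 else e2
      o <- if (e1$type == "ret") e2 else e1
      other <- if (o$tail == v) o$head else o$tail
      new <- data.frame(id = e1$id, tail = other, head = r$head, type = "ret")
    } else {
      a <- if (e1$tail == v) e1$head else e1$tail
      b <- if (e2$tail == v) e2$head else e2$tail
      new <- data.frame(id = e1$id, tail = a, head = b, type = "tree")
    }
    ed <- rbind(ed[-inc, ], new)
    vs <- setdiff(vs, v)
  }
  lv <- unlist(as.list(leaves))
  lv <- lv[order_labels(names(lv))]
  sdnet(vs, ed, lv)
}

#' Write a network as extended Newick
#'
#' A valid rooting is searched among the tree edges: the root is placed on
#' an edge such that orienting everything away from it agrees with the
#' stored reticulation-edge directions.
#'
#' @param net an `sdnet`.
#' @return single eNewick string (with trailing semicolon).
#' @export
write_enewick <- function(net) {
  e <- net$edges
  rv <- ret_vertices(net)
  leaf_of <- stats::setNames(names(net$leaves), unname(net$leaves))
  for (i in which(e$type == "tree")) {
    res <- try(enewick_from_root(net, i), silent = TRUE)
    if (!inherits(res, "try-error")) return(res)
  }
  stop("no valid rooting found")
}

enewick_from_root <- function(net, root_edge) {
  e <- net$edges
  rv <- ret_vertices(net)
  leaf_of <- stats::setNames(names(net$leaves), unname(net$leaves))
  htag <- stats::setNames(seq_along(rv), rv)
  visited <- character(0)
  descend <- function(v, via) {
    if (v %in% rv) {
      if (v %in% visited) return(paste0("#H", htag[[v]]))
      visited <<- c(visited, v)
      # both reticulation edges must arrive at v
      inc <- which((e$tail == v | e$head == v) & e$id != via)
      down <- inc[e$type[inc] != "ret"]
      if (length(which(e$type == "ret" & e$head == v & e$id == via)) != 1L)
        stop("inconsistent rooting")
      parts <- vapply(down, function(i) {
        child <- if (e$tail[i] == v) e$head[i] else e$tail[i]
        descend(child, e$id[i])
      }, "")
      if (length(parts) == 0L)
        return(paste0(if (v %in% names(leaf_of)) leaf_of[[v]] else "",
                      "#H", htag[[v]]))
      return(paste0("(", paste(parts, collapse = ","), ")#H", htag[[v]]))
    }
    inc <- which((e$tail == v | e$head == v) & e$id != via)
    if (length(inc) == 0L) return(leaf_of[[v]])
    # a reticulation edge may only be traversed tail -> head
    parts <- vapply(inc, function(i) {
      if (e$type[i] == "ret" && e$head[i] == v) stop("inconsistent rooting")
      child <- if (e$tail[i] == v) e$head[i] else e$tail[i]
      descend(child, e$id[i])
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  i <- root_edge
  left <- descend(e$tail[i], e$id[i])
  right <- descend(e$head[i], e$id[i])
  if (length(visited) != length(rv)) stop("inconsistent rooting")
  paste0("(", left, ",", right, ");")
}

#' Bundled figure fixtures
#'
#' `fig1_sunlet()` is the leaf-labelled 4-sunlet with the edge numbering
#' and orientations used for the worked parameterization example;
#' `fig3_network()` is the 6-leaf level-1 network with one 4-cycle whose
#' cut edge `e` separates a 4-sunlet (leaves 1-3) from a 4-leaf tree
#' (leaves 4-6).
#'
#' @return an `sdnet`.
#' @export
fig1_sunlet <- function() make_sunlet(4L)

#' @rdname fig1_sunlet
#' @export
fig3_network <- function() {
  sun <- make_sunlet(4L)
  e <- sun$edges
  # replace leaf 4's pendant edge by the cut edge e into a 4-leaf tree
  e <- e[e$id != "e4", ]
  e <- rbind(e,
             data.frame(id = "e", tail = "a", head = "v4", type = "tree"),
             data.frame(id = "f1", tail = "a", head = "y4", type = "tree"),
             data.frame(id = "f2", tail = "a", head = "b", type = "tree"),
             data.frame(id = "f3", tail = "b", head = "y5", type = "tree"),
             data.frame(id = "f4", tail = "b", head = "y6", type = "tree"))
  vs <- c(setdiff(sun$vertices, "x4"), "a", "b", "y4", "y5", "y6")
  leaves <- stats::setNames(c("x1", "x2", "x3", "y4", "y5", "y6"),
                            as.character(1:6))
  sdnet(vs, e, leaves)
}
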