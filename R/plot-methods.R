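# Quick-look base-graphics plots of the profile objects.

#' @describeIn accessors plot a pathway's radius profile R(s).
#' @param y ignored.
#' @export
setMethod("plot", signature("Pathway", "missing"), function(x, y, ...) {
  plot(x@s, x@radius, type = "l", xlab = "s (nm)",
       ylab = "pore radius R(s) (nm)", ...)
  abline(h = 0.14, lty = 3)   # radius of one water molecule
  invisible(NULL)
})

#' @describeIn accessors plot a density profile with a +/- 1 SD band.
#' @export
setMethod("plot", signature("DensityProfile", "missing"), function(x, y, ...) {
  ok <- !x@missing & !is.na(x@density)
  plot(x@sGrid[ok], x@density[ok], type = "n", xlab = "s (nm)",
       ylab = expression(n(s) ~ (nm^-3)), ...)
  polygon(c(x@sGrid[ok], rev(x@sGrid[ok])),
          c(pmax(x@density[ok] - x@sd[ok], 0),
            rev(x@density[ok] + x@sd[ok])),
          col = "grey85", border = NA)
  lines(x@sGrid[ok], x@density[ok])
  invisible(NULL)
})

#' @describeIn accessors plot a free-energy profile (capped points dotted).
#' @export
setMethod("plot", signature("FreeEnergyProfile", "missing"),
          function(x, y, ...) {
  plot(x@sGrid, x@G, type = "l", xlab = "s (nm)",
       ylab = expression(G(s) ~ (k[B] * T)), ...)
  if (any(x@capped))
    lines(x@sGrid[x@capped], x@G[x@capped], type = "p", pch = 20, cex = 0.4)
  abline(h = 0, lty = 3)
  invisible(NULL)
})

#' @describeIn accessors plot gate occupancy over time, shaded by state.
#' @export
setMethod("plot", signature("WettingSeries", "missing"), function(x, y, ...) {
  plot(x@time, x@occupancy, type = "s", xlab = "time (ns)",
       ylab = "gate occupancy (waters)", ...)
  abline(h = x@threshold - 0.5, lty = 3)
  invisible(NULL)
})
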