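# Minimal spiral-wave simulation: Barkley kinetics on a 100x100 box
# (one-node void rind), cross-field initial conditions, periodic point
# records. Run with:  inst/cli/cardiogrid run inst/extdata/spiral.yaml
state: {nx: 102, ny: 102, nv: 3, h: 0.4}
globals: {begin: 0, out: 0, end: 0, nsteps: 1000}
macros: {u: 0, v: 1, i: 2}
devices:
  - {device: k_func, nowhere: yes, name: timing,
     pgm: "begin = eq(t,0); out = eq(mod(t,10),0); end = ge(t,nsteps)"}
  - {device: k_func, when: begin, name: IC,
     pgm: "u[u] = gt(y,50); u[v] = 0.4*lt(x,50)"}
  - {device: record, when: out, file: "spiral-history.dat",
     v0: "[u]", v1: "[v]",
     space: {x0: 10, x1: 10, y0: 20, y1: 20, z0: 0, z1: 0}}
  - {device: stop, when: end}
  - {device: diffstep, v0: "[u]", v1: "[i]", Dpar: 1, hx: 0.4, ht: 0.02}
  - {device: euler, v0: "[u]", v1: "[v]", ht: 0.02, ode: fhnbkl,
     par: {a: 0.8, b: 0.01, eps: 0.02}}
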