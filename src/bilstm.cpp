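// Two-layer bidirectional LSTM + two fully connected layers with sigmoid
// output, per-residue. Forward, weighted cross-entropy loss, and full
// backpropagation through time, for equal-length residue windows.
//
// Parameter layout (flat vector), PyTorch LSTM convention (two bias
// vectors per direction; gate order i, f, g, o):
//   for layer in {1, 2}: for dir in {fwd, bwd}:
//     W (4h x in), U (4h x h), b_ih (4h), b_hh (4h)
//   FC1: W1 (f x 2*h2), b1 (f)
//   FC2: W2 (1 x f), b2 (1)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct LstmDirPar {
  mat W, U;
  vec b;  // b_ih + b_hh combined for compute; both slots get the same grad
};

struct LstmDirGrad {
  mat W, U;
  vec b;
  void init(int in, int h) {
    W.zeros(4 * h, in);
    U.zeros(4 * h, h);
    b.zeros(4 * h);
  }
};

struct LstmDirCache {
  cube gates;   // 4h x B x T (post-activation: i, f, g, o stacked)
  cube cstate;  // h x B x T
  cube hstate;  // h x B x T
};

int lstm_dir_nparam(int in, int h) { return 4 * h * (in + h + 2); }

// read one direction's parameters (copies; read-only use)
LstmDirPar read_lstm(const double* p, int& off, int in, int h) {
  LstmDirPar out;
  out.W = mat(p + off, 4 * h, in); off += 4 * h * in;
  out.U = mat(p + off, 4 * h, h);  off += 4 * h * h;
  vec b_ih(p + off, 4 * h); off += 4 * h;
  vec b_hh(p + off, 4 * h); off += 4 * h;
  out.b = b_ih + b_hh;
  return out;
}

// write one direction's gradient into the flat vector
void pack_lstm(double* g, int& off, const LstmDirGrad& gr) {
  std::memcpy(g + off, gr.W.memptr(), sizeof(double) * gr.W.n_elem); off += gr.W.n_elem;
  std::memcpy(g + off, gr.U.memptr(), sizeof(double) * gr.U.n_elem); off += gr.U.n_elem;
  std::memcpy(g + off, gr.b.memptr(), sizeof(double) * gr.b.n_elem); off += gr.b.n_elem;
  std::memcpy(g + off, gr.b.memptr(), sizeof(double) * gr.b.n_elem); off += gr.b.n_elem;
}

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Run one LSTM direction over X (in x B x T). If rev, time runs T-1..0.
cube lstm_dir_forward(const cube& X, const LstmDirPar& par, int h, bool rev,
                      LstmDirCache& cache) {
  const int B = X.n_cols, T = X.n_slices, in = X.n_rows;
  cache.gates.set_size(4 * h, B, T);
  cache.cstate.set_size(h, B, T);
  cache.hstate.set_size(h, B, T);

  // all input projections in one gemm
  const mat Xflat(const_cast<double*>(X.memptr()), in, B * T, false, true);
  mat proj = par.W * Xflat;  // 4h x (B*T)

  mat hprev(h, B, fill::zeros), cprev(h, B, fill::zeros);
  for (int step = 0; step < T; ++step) {
    int t = rev ? (T - 1 - step) : step;
    mat a = proj.cols(t * B, t * B + B - 1);
    a += par.U * hprev;
    a.each_col() += par.b;
    mat gi = sigm(a.rows(0, h - 1));
    mat gf = sigm(a.rows(h, 2 * h - 1));
    mat gg = tanh(a.rows(2 * h, 3 * h - 1));
    mat go = sigm(a.rows(3 * h, 4 * h - 1));
    mat c = gf % cprev + gi % gg;
    mat hh = go % tanh(c);
    cache.gates.slice(t).rows(0, h - 1) = gi;
    cache.gates.slice(t).rows(h, 2 * h - 1) = gf;
    cache.gates.slice(t).rows(2 * h, 3 * h - 1) = gg;
    cache.gates.slice(t).rows(3 * h, 4 * h - 1) = go;
    cache.cstate.slice(t) = c;
    cache.hstate.slice(t) = hh;
    hprev = hh;
    cprev = c;
  }
  return cache.hstate;  // h x B x T
}

// Backprop one direction. dH: h x B x T (grad wrt this direction's output).
// Accumulates into gr; returns dX (in x B x T).
cube lstm_dir_backward(const cube& X, const LstmDirPar& par, LstmDirGrad& gr,
                       int h, bool rev, const LstmDirCache& cache, const cube& dH) {
  const int B = X.n_cols, T = X.n_slices, in = X.n_rows;
  mat dh_next(h, B, fill::zeros), dc_next(h, B, fill::zeros);
  mat dA(4 * h, B * T, fill::zeros);  // pre-activation grads

  for (int step = T - 1; step >= 0; --step) {
    int t = rev ? (T - 1 - step) : step;
    int tprev = rev ? (T - step) : (step - 1);  // protein-time index of previous step

    mat gi = cache.gates.slice(t).rows(0, h - 1);
    mat gf = cache.gates.slice(t).rows(h, 2 * h - 1);
    mat gg = cache.gates.slice(t).rows(2 * h, 3 * h - 1);
    mat go = cache.gates.slice(t).rows(3 * h, 4 * h - 1);
    mat tc = tanh(mat(cache.cstate.slice(t)));
    mat cprev(h, B, fill::zeros), hprev(h, B, fill::zeros);
    if (step > 0) {
      cprev = cache.cstate.slice(tprev);
      hprev = cache.hstate.slice(tprev);
    }

    mat dh = dH.slice(t) + dh_next;
    mat dgo = dh % tc;
    mat dc = dc_next + dh % go % (1.0 - tc % tc);
    mat dgi = dc % gg;
    mat dgg = dc % gi;
    mat dgf = dc % cprev;
    dc_next = dc % gf;

    mat da(4 * h, B);
    da.rows(0, h - 1) = dgi % gi % (1.0 - gi);
    da.rows(h, 2 * h - 1) = dgf % gf % (1.0 - gf);
    da.rows(2 * h, 3 * h - 1) = dgg % (1.0 - gg % gg);
    da.rows(3 * h, 4 * h - 1) = dgo % go % (1.0 - go);

    dA.cols(t * B, t * B + B - 1) = da;
    gr.U += da * hprev.t();
    gr.b += sum(da, 1);
    dh_next = par.U.t() * da;
  }
  const mat Xflat(const_cast<double*>(X.memptr()), in, B * T, false, true);
  gr.W += dA * Xflat.t();
  mat dXflat = par.W.t() * dA;  // in x (B*T)
  cube dX(dXflat.memptr(), in, B, T);
  return dX;
}

cube stack_bidir(const cube& hf, const cube& hb) {
  cube out(hf.n_rows * 2, hf.n_cols, hf.n_slices);
  for (unsigned t = 0; t < hf.n_slices; ++t) {
    out.slice(t).rows(0, hf.n_rows - 1) = hf.slice(t);
    out.slice(t).rows(hf.n_rows, 2 * hf.n_rows - 1) = hb.slice(t);
  }
  return out;
}

cube onehot_cube(const Rcpp::IntegerMatrix& codes, int d) {
  const int T = codes.nrow(), B = codes.ncol();
  cube X(d, B, T, fill::zeros);
  for (int t = 0; t < T; ++t)
    for (int b = 0; b < B; ++b) {
      int c = codes(t, b);
      if (c > 0) X(c - 1, b, t) = 1.0;
    }
  return X;
}

cube dropout_mask(int r, int B, int T, double rate) {
  cube m(r, B, T);
  double keep = 1.0 - rate;
  for (uword i = 0; i < m.n_elem; ++i)
    m(i) = (R::unif_rand() < keep) ? (1.0 / keep) : 0.0;
  return m;
}

}  // namespace

// [[Rcpp::export]]
int bilstm_nparam_cpp(int d, int h1, int h2, int f) {
  return 2 * lstm_dir_nparam(d, h1) + 2 * lstm_dir_nparam(2 * h1, h2) +
         f * (2 * h2 + 1) + f + 1;
}

// Forward (and optionally backward) pass on a batch of equal-length windows.
// codes: T x B integer matrix, 1..20 residues, 0 = 'X' padding.
// y, excl: T x B labels and loss-exclusion flags (used when want_loss).
// [[Rcpp::export]]
Rcpp::List bilstm_run_cpp(const Rcpp::IntegerMatrix& codes,
                          const Rcpp::NumericVector& params,
                          int h1, int h2, int f,
                          double dropout, bool training,
                          const Rcpp::NumericMatrix& y,
                          const Rcpp::LogicalMatrix& excl,
                          bool want_loss, bool want_grad) {
  const int d = 20;
  const int T = codes.nrow(), B = codes.ncol();
  if ((int)params.size() != bilstm_nparam_cpp(d, h1, h2, f))
    Rcpp::stop("parameter vector has wrong length");

  const double* p = params.begin();
  int off = 0;
  LstmDirPar l1f = read_lstm(p, off, d, h1);
  LstmDirPar l1b = read_lstm(p, off, d, h1);
  LstmDirPar l2f = read_lstm(p, off, 2 * h1, h2);
  LstmDirPar l2b = read_lstm(p, off, 2 * h1, h2);
  mat W1(p + off, f, 2 * h2); off += f * 2 * h2;
  vec b1(p + off, f); off += f;
  mat W2(p + off, 1, f); off += f;
  double b2 = p[off];

  cube X = onehot_cube(codes, d);

  LstmDirCache c1f, c1b, c2f, c2b;
  cube h1fwd = lstm_dir_forward(X, l1f, h1, false, c1f);
  cube h1bwd = lstm_dir_forward(X, l1b, h1, true, c1b);
  cube H1 = stack_bidir(h1fwd, h1bwd);  // 2h1 x B x T

  bool use_drop = training && dropout > 0.0;
  cube m1, m2, m3;
  if (use_drop) { m1 = dropout_mask(2 * h1, B, T, dropout); H1 %= m1; }

  cube h2fwd = lstm_dir_forward(H1, l2f, h2, false, c2f);
  cube h2bwd = lstm_dir_forward(H1, l2b, h2, true, c2b);
  cube H2 = stack_bidir(h2fwd, h2bwd);  // 2h2 x B x T
  if (use_drop) { m2 = dropout_mask(2 * h2, B, T, dropout); H2 %= m2; }

  mat H2flat(H2.memptr(), 2 * h2, B * T, false, true);
  mat A1 = W1 * H2flat;  // f x (B*T)
  A1.each_col() += b1;
  mat R1 = clamp(A1, 0.0, datum::inf);  // ReLU
  mat R1d = R1;
  if (use_drop) {
    m3 = dropout_mask(f, B, T, dropout);
    mat m3flat(m3.memptr(), f, B * T, false, true);
    R1d %= m3flat;
  }
  rowvec Z = W2 * R1d + b2;  // 1 x (B*T), column index = t*B + b
  rowvec P = 1.0 / (1.0 + exp(-Z));

  Rcpp::NumericMatrix scores(T, B);
  for (int t = 0; t < T; ++t)
    for (int b = 0; b < B; ++b) scores(t, b) = P(t * B + b);

  if (!want_loss)
    return Rcpp::List::create(Rcpp::Named("scores") = scores);

  // weighted cross-entropy over unmasked positions
  const double eps = 1e-7;
  double n = 0.0, n_deg = 0.0;
  for (int t = 0; t < T; ++t)
    for (int b = 0; b < B; ++b)
      if (!excl(t, b)) { n += 1.0; n_deg += y(t, b); }
  if (n == 0.0) Rcpp::stop("no unmasked residues: loss undefined");

  double loss = 0.0;
  rowvec dZ(B * T, fill::zeros);
  for (int t = 0; t < T; ++t)
    for (int b = 0; b < B; ++b) {
      if (excl(t, b)) continue;
      int k = t * B + b;
      double pc = std::min(std::max((double)P(k), eps), 1.0 - eps);
      double yy = y(t, b);
      loss -= (n - n_deg) * yy * std::log(pc) + n_deg * (1.0 - yy) * std::log(1.0 - pc);
      dZ(k) = -((n - n_deg) * yy * (1.0 - pc) - n_deg * (1.0 - yy) * pc);
    }
  loss /= n * n;
  dZ /= n * n;

  if (!want_grad)
    return Rcpp::List::create(Rcpp::Named("scores") = scores,
                              Rcpp::Named("loss") = loss);

  // ---- backward ----
  LstmDirGrad g1f, g1b, g2f, g2b;
  g1f.init(d, h1); g1b.init(d, h1);
  g2f.init(2 * h1, h2); g2b.init(2 * h1, h2);

  mat dR1d = W2.t() * dZ;  // f x (B*T)
  mat gW2 = dZ * R1d.t();  // 1 x f
  double gb2 = accu(dZ);
  if (use_drop) {
    mat m3flat(m3.memptr(), f, B * T, false, true);
    dR1d %= m3flat;
  }
  mat relu_gate = conv_to<mat>::from(A1 > 0.0);
  mat dA1 = dR1d % relu_gate;
  mat gW1 = dA1 * H2flat.t();
  vec gb1 = sum(dA1, 1);
  mat dH2flat = W1.t() * dA1;  // 2h2 x (B*T)
  cube dH2(dH2flat.memptr(), 2 * h2, B, T);
  if (use_drop) dH2 %= m2;

  cube dH2f(h2, B, T), dH2b(h2, B, T);
  for (int t = 0; t < T; ++t) {
    dH2f.slice(t) = dH2.slice(t).rows(0, h2 - 1);
    dH2b.slice(t) = dH2.slice(t).rows(h2, 2 * h2 - 1);
  }
  cube dH1 = lstm_dir_backward(H1, l2f, g2f, h2, false, c2f, dH2f);
  dH1 += lstm_dir_backward(H1, l2b, g2b, h2, true, c2b, dH2b);
  if (use_drop) dH1 %= m1;

  cube dH1f(h1, B, T), dH1b(h1, B, T);
  for (int t = 0; t < T; ++t) {
    dH1f.slice(t) = dH1.slice(t).rows(0, h1 - 1);
    dH1b.slice(t) = dH1.slice(t).rows(h1, 2 * h1 - 1);
  }
  lstm_dir_backward(X, l1f, g1f, h1, false, c1f, dH1f);
  lstm_dir_backward(X, l1b, g1b, h1, true, c1b, dH1b);

  Rcpp::NumericVector grad(params.size());
  double* g = grad.begin();
  off = 0;
  pack_lstm(g, off, g1f);
  pack_lstm(g, off, g1b);
  pack_lstm(g, off, g2f);
  pack_lstm(g, off, g2b);
  std::memcpy(g + off, gW1.memptr(), sizeof(double) * gW1.n_elem); off += gW1.n_elem;
  std::memcpy(g + off, gb1.memptr(), sizeof(double) * gb1.n_elem); off += gb1.n_elem;
  std::memcpy(g + off, gW2.memptr(), sizeof(double) * gW2.n_elem); off += gW2.n_elem;
  g[off] = gb2;

  return Rcpp::List::create(Rcpp::Named("scores") = scores,
                            Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}
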