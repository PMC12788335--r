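// Per-timestep binary sequence labelling with stacked inception blocks.
//
// Layout conventions:
//  - A batch of N windows of length T over C channels is one matrix of size
//    C x (N*T); the columns of window n are the contiguous block [n*T, (n+1)*T).
//    Convolutions are "same"-padded per window, so no information leaks across
//    window boundaries.
//  - im2col for an odd kernel k stacks the k temporal offsets row-wise
//    (offset-major, channel within offset), so a conv is one GEMM:
//    out = W (C_out x C_in*k) * im2col(x) (C_in*k x N*T).
//
// Batch norm uses biased batch variance for normalisation and for the running
// statistics (momentum 0.1); eval mode uses the running statistics.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::stop;

static const double BN_EPS = 1e-5;

// ---------------------------------------------------------------------------
// weights

struct BlockW {
  mat W1, Wb3, W3, Wb5, W5, Wb7, W7, Wr;
  vec gi, bi, gr, br;      // BN affine (inception path, residual path)
  vec rmi, rvi, rmr, rvr;  // BN running mean/var
};

struct Net {
  std::vector<BlockW> blocks;
  mat Wh;  // 1 x 128
  vec bh;  // head bias, length 1
};

static vec as_vec(const List& l, const char* nm) {
  return Rcpp::as<vec>(l[nm]);
}
static mat as_mat(const List& l, const char* nm) {
  return Rcpp::as<mat>(l[nm]);
}

static Net parse_net(const List& weights) {
  Net net;
  List blocks = weights["blocks"];
  for (int b = 0; b < blocks.size(); ++b) {
    List bl = blocks[b];
    BlockW w;
    w.W1  = as_mat(bl, "W1");  w.Wb3 = as_mat(bl, "Wb3"); w.W3 = as_mat(bl, "W3");
    w.Wb5 = as_mat(bl, "Wb5"); w.W5  = as_mat(bl, "W5");
    w.Wb7 = as_mat(bl, "Wb7"); w.W7  = as_mat(bl, "W7");
    w.Wr  = as_mat(bl, "Wr");
    w.gi = as_vec(bl, "gi"); w.bi = as_vec(bl, "bi");
    w.gr = as_vec(bl, "gr"); w.br = as_vec(bl, "br");
    w.rmi = as_vec(bl, "rmi"); w.rvi = as_vec(bl, "rvi");
    w.rmr = as_vec(bl, "rmr"); w.rvr = as_vec(bl, "rvr");
    net.blocks.push_back(std::move(w));
  }
  List head = weights["head"];
  net.Wh = as_mat(head, "W");
  net.bh = vec{Rcpp::as<double>(head["b"])};
  return net;
}

static List net_to_list(const Net& net) {
  List blocks(net.blocks.size());
  for (size_t b = 0; b < net.blocks.size(); ++b) {
    const BlockW& w = net.blocks[b];
    blocks[b] = List::create(
      Named("W1") = w.W1, Named("Wb3") = w.Wb3, Named("W3") = w.W3,
      Named("Wb5") = w.Wb5, Named("W5") = w.W5,
      Named("Wb7") = w.Wb7, Named("W7") = w.W7, Named("Wr") = w.Wr,
      Named("gi") = w.gi, Named("bi") = w.bi,
      Named("gr") = w.gr, Named("br") = w.br,
      Named("rmi") = w.rmi, Named("rvi") = w.rvi,
      Named("rmr") = w.rmr, Named("rvr") = w.rvr);
  }
  return List::create(Named("blocks") = blocks,
                      Named("head") = List::create(Named("W") = net.Wh,
                                                   Named("b") = net.bh(0)));
}

// ---------------------------------------------------------------------------
// conv plumbing

static mat im2col(const mat& X, int k, int n_win, int T) {
  const int C = X.n_rows;
  const int h = (k - 1) / 2;
  mat out(C * k, X.n_cols, fill::zeros);
  for (int o = -h; o <= h; ++o) {
    const int r0 = (o + h) * C;
    const int t_lo = std::max(0, -o);
    const int t_hi = T - 1 - std::max(0, o);
    if (t_lo > t_hi) continue;
    for (int n = 0; n < n_win; ++n) {
      out.submat(r0, n * T + t_lo, r0 + C - 1, n * T + t_hi) =
        X.cols(n * T + t_lo + o, n * T + t_hi + o);
    }
  }
  return out;
}

static mat col2im(const mat& cols, int C, int k, int n_win, int T) {
  const int h = (k - 1) / 2;
  mat dX(C, cols.n_cols, fill::zeros);
  for (int o = -h; o <= h; ++o) {
    const int r0 = (o + h) * C;
    const int t_lo = std::max(0, -o);
    const int t_hi = T - 1 - std::max(0, o);
    if (t_lo > t_hi) continue;
    for (int n = 0; n < n_win; ++n) {
      dX.cols(n * T + t_lo + o, n * T + t_hi + o) +=
        cols.submat(r0, n * T + t_lo, r0 + C - 1, n * T + t_hi);
    }
  }
  return dX;
}

// ---------------------------------------------------------------------------
// batch norm

static mat bn_forward_train(const mat& X, const vec& g, const vec& b,
                            vec& rm, vec& rv, double mom,
                            mat& xhat, vec& istd) {
  vec mu = mean(X, 1);
  mat Xc = X.each_col() - mu;
  vec v = mean(square(Xc), 1);
  istd = 1.0 / sqrt(v + BN_EPS);
  xhat = Xc.each_col() % istd;
  mat out = xhat.each_col() % g;
  out.each_col() += b;
  rm = (1.0 - mom) * rm + mom * mu;
  rv = (1.0 - mom) * rv + mom * v;
  return out;
}

static mat bn_forward_eval(const mat& X, const vec& g, const vec& b,
                           const vec& rm, const vec& rv) {
  vec istd = 1.0 / sqrt(rv + BN_EPS);
  mat out = X.each_col() - rm;
  out.each_col() %= (istd % g);
  out.each_col() += b;
  return out;
}

static mat bn_backward(const mat& dout, const mat& xhat, const vec& istd,
                       const vec& g, vec& dg, vec& db) {
  const double M = (double)dout.n_cols;
  dg = sum(dout % xhat, 1);
  db = sum(dout, 1);
  mat dxhat = dout.each_col() % g;
  vec s1 = sum(dxhat, 1);
  vec s2 = sum(dxhat % xhat, 1);
  mat dX = dxhat * M;
  dX.each_col() -= s1;
  dX -= xhat.each_col() % s2;
  dX.each_col() %= (istd / M);
  return dX;
}

// ---------------------------------------------------------------------------
// block forward / backward

struct BlockCache {
  mat x, z3, z5, z7, xhat_i, xhat_r, y;
  vec istd_i, istd_r;
};

struct BlockG {
  mat dW1, dWb3, dW3, dWb5, dW5, dWb7, dW7, dWr;
  vec dgi, dbi, dgr, dbr;
};

static mat block_forward(const mat& x, BlockW& w, int n_win, int T,
                         bool training, double mom, BlockCache* c) {
  mat b1 = w.W1 * x;
  mat z3 = w.Wb3 * x;
  mat z5 = w.Wb5 * x;
  mat z7 = w.Wb7 * x;
  mat P = join_cols(join_cols(b1, w.W3 * im2col(z3, 3, n_win, T)),
                    join_cols(w.W5 * im2col(z5, 5, n_win, T),
                              w.W7 * im2col(z7, 7, n_win, T)));
  mat Rl = w.Wr * x;
  mat I, Rn;
  if (training) {
    c->x = x; c->z3 = std::move(z3); c->z5 = std::move(z5); c->z7 = std::move(z7);
    I  = bn_forward_train(P,  w.gi, w.bi, w.rmi, w.rvi, mom, c->xhat_i, c->istd_i);
    Rn = bn_forward_train(Rl, w.gr, w.br, w.rmr, w.rvr, mom, c->xhat_r, c->istd_r);
  } else {
    I  = bn_forward_eval(P,  w.gi, w.bi, w.rmi, w.rvi);
    Rn = bn_forward_eval(Rl, w.gr, w.br, w.rmr, w.rvr);
  }
  mat y = clamp(I + Rn, 0.0, datum::inf);
  if (training) c->y = y;
  return y;
}

static mat block_backward(const mat& dy, const BlockW& w, const BlockCache& c,
                          BlockG& g, int n_win, int T) {
  mat dS = dy;
  dS.elem(find(c.y <= 0.0)).zeros();

  mat dP  = bn_backward(dS, c.xhat_i, c.istd_i, w.gi, g.dgi, g.dbi);
  mat dRl = bn_backward(dS, c.xhat_r, c.istd_r, w.gr, g.dgr, g.dbr);

  g.dWr = dRl * c.x.t();
  mat dx = w.Wr.t() * dRl;

  mat db1 = dP.rows(0, 31);
  g.dW1 = db1 * c.x.t();
  dx += w.W1.t() * db1;

  auto branch = [&](const mat& dc, const mat& z, const mat& W, const mat& Wb,
                    int k, mat& dW, mat& dWb) {
    mat cols = im2col(z, k, n_win, T);
    dW = dc * cols.t();
    mat dz = col2im(W.t() * dc, 32, k, n_win, T);
    dWb = dz * c.x.t();
    dx += Wb.t() * dz;
  };
  branch(dP.rows(32, 63),  c.z3, w.W3, w.Wb3, 3, g.dW3, g.dWb3);
  branch(dP.rows(64, 95),  c.z5, w.W5, w.Wb5, 5, g.dW5, g.dWb5);
  branch(dP.rows(96, 127), c.z7, w.W7, w.Wb7, 7, g.dW7, g.dWb7);
  return dx;
}

// ---------------------------------------------------------------------------
// full forward

static rowvec net_logits_eval(Net& net, const mat& x0, int n_win, int T) {
  mat y = x0;
  for (size_t b = 0; b < net.blocks.size(); ++b) {
    y = block_forward(y, net.blocks[b], n_win, T, false, 0.0, nullptr);
  }
  rowvec z = net.Wh * y;
  z += net.bh(0);
  return z;
}

static rowvec net_logits_train(Net& net, const mat& x0, int n_win, int T,
                               double mom, std::vector<BlockCache>& caches,
                               mat& y_last) {
  mat y = x0;
  caches.resize(net.blocks.size());
  for (size_t b = 0; b < net.blocks.size(); ++b) {
    y = block_forward(y, net.blocks[b], n_win, T, true, mom, &caches[b]);
  }
  y_last = y;
  rowvec z = net.Wh * y;
  z += net.bh(0);
  return z;
}

// stable BCE-with-logits; also writes dL/dz into dz if non-null
static double bce_with_logits(const rowvec& z, const rowvec& y, rowvec* dz) {
  rowvec zabs = abs(z);
  rowvec loss = log1p(exp(-zabs)) + clamp(z, 0.0, datum::inf) - z % y;
  if (dz) {
    rowvec p = 1.0 / (1.0 + exp(-z));
    *dz = (p - y) / (double)z.n_elem;
  }
  return accu(loss) / (double)z.n_elem;
}

// ---------------------------------------------------------------------------
// array plumbing: R array N x C x T  ->  C x (N*T)

static mat unpack_windows(const Rcpp::NumericVector& X, int& N, int& C, int& T) {
  Rcpp::IntegerVector dim = X.attr("dim");
  if (dim.size() != 3) stop("expected a 3-d array N x C x T");
  N = dim[0]; C = dim[1]; T = dim[2];
  mat out(C, (size_t)N * T);
  const double* px = X.begin();
  for (int t = 0; t < T; ++t)
    for (int c = 0; c < C; ++c)
      for (int n = 0; n < N; ++n)
        out(c, (size_t)n * T + t) = px[n + (size_t)N * c + (size_t)N * C * t];
  return out;
}

static rowvec unpack_labels(const Rcpp::NumericMatrix& Y) {
  const int N = Y.nrow(), T = Y.ncol();
  rowvec out((size_t)N * T);
  for (int t = 0; t < T; ++t)
    for (int n = 0; n < N; ++n)
      out((size_t)n * T + t) = Y(n, t);
  return out;
}

// ---------------------------------------------------------------------------
// Adam

struct Adam {
  std::vector<mat> m_m, v_m;
  std::vector<vec> m_v, v_v;
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;

  void init(const std::vector<mat*>& pm, const std::vector<vec*>& pv) {
    for (mat* p : pm) { m_m.emplace_back(size(*p), fill::zeros); v_m.emplace_back(size(*p), fill::zeros); }
    for (vec* p : pv) { m_v.emplace_back(size(*p), fill::zeros); v_v.emplace_back(size(*p), fill::zeros); }
  }
  void step(std::vector<mat*>& pm, std::vector<mat*>& gm,
            std::vector<vec*>& pv, std::vector<vec*>& gv) {
    ++t;
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < pm.size(); ++i) {
      m_m[i] = b1 * m_m[i] + (1 - b1) * (*gm[i]);
      v_m[i] = b2 * v_m[i] + (1 - b2) * square(*gm[i]);
      *pm[i] -= lr * (m_m[i] / c1) / (sqrt(v_m[i] / c2) + eps);
    }
    for (size_t i = 0; i < pv.size(); ++i) {
      m_v[i] = b1 * m_v[i] + (1 - b1) * (*gv[i]);
      v_v[i] = b2 * v_v[i] + (1 - b2) * square(*gv[i]);
      *pv[i] -= lr * (m_v[i] / c1) / (sqrt(v_v[i] / c2) + eps);
    }
  }
};

static void collect_params(Net& net, std::vector<mat*>& pm, std::vector<vec*>& pv) {
  for (BlockW& w : net.blocks) {
    pm.push_back(&w.W1); pm.push_back(&w.Wb3); pm.push_back(&w.W3);
    pm.push_back(&w.Wb5); pm.push_back(&w.W5);
    pm.push_back(&w.Wb7); pm.push_back(&w.W7); pm.push_back(&w.Wr);
    pv.push_back(&w.gi); pv.push_back(&w.bi);
    pv.push_back(&w.gr); pv.push_back(&w.br);
  }
  pm.push_back(&net.Wh);
  pv.push_back(&net.bh);
}

// ---------------------------------------------------------------------------
// exported: eval-mode forward

// [[Rcpp::export(name = ".cpp_predict")]]
Rcpp::NumericMatrix cpp_predict(List weights, Rcpp::NumericVector X, int chunk = 256) {
  Net net = parse_net(weights);
  int N, C, T;
  mat Xall = unpack_windows(X, N, C, T);
  if ((int)net.blocks.front().W1.n_cols != C)
    stop("input has %d channels but the model expects %d", C,
         (int)net.blocks.front().W1.n_cols);
  Rcpp::NumericMatrix out(N, T);
  for (int lo = 0; lo < N; lo += chunk) {
    int hi = std::min(lo + chunk, N);
    mat xb = Xall.cols((size_t)lo * T, (size_t)hi * T - 1);
    rowvec z = net_logits_eval(net, xb, hi - lo, T);
    rowvec p = 1.0 / (1.0 + exp(-z));
    for (int n = lo; n < hi; ++n)
      for (int t = 0; t < T; ++t)
        out(n, t) = p((size_t)(n - lo) * T + t);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_block_forward")]]
Rcpp::NumericMatrix cpp_block_forward(List block_weights, Rcpp::NumericMatrix x) {
  List wl = List::create(
    Named("blocks") = List::create(block_weights),
    Named("head") = List::create(Named("W") = Rcpp::NumericMatrix(1, 128),
                                 Named("b") = 0.0));
  Net net = parse_net(wl);
  mat xin = Rcpp::as<mat>(x);
  mat y = block_forward(xin, net.blocks[0], 1, xin.n_cols, false, 0.0, nullptr);
  return Rcpp::wrap(y);
}

static double eval_loss_chunked(Net& net, const mat& Xall, const rowvec& Yall,
                                int N, int T, int chunk) {
  double tot = 0.0;
  for (int lo = 0; lo < N; lo += chunk) {
    int hi = std::min(lo + chunk, N);
    mat xb = Xall.cols((size_t)lo * T, (size_t)hi * T - 1);
    rowvec yb = Yall.subvec((size_t)lo * T, (size_t)hi * T - 1);
    rowvec z = net_logits_eval(net, xb, hi - lo, T);
    tot += bce_with_logits(z, yb, nullptr) * (double)(hi - lo);
  }
  return tot / (double)N;
}

// exported: loss + analytic gradients at current weights (for testing)

// [[Rcpp::export(name = ".cpp_loss_grads")]]
List cpp_loss_grads(List weights, Rcpp::NumericVector X, Rcpp::NumericMatrix Y) {
  Net net = parse_net(weights);
  int N, C, T;
  mat Xall = unpack_windows(X, N, C, T);
  rowvec Yall = unpack_labels(Y);

  std::vector<BlockCache> caches;
  mat y_last;
  rowvec z = net_logits_train(net, Xall, N, T, 0.1, caches, y_last);
  rowvec dz;
  double loss = bce_with_logits(z, Yall, &dz);

  // dz is 1 x M; y_last is 128 x M; head W is 1 x 128
  mat dWh = mat(dz) * y_last.t();
  double dbh = accu(dz);
  mat dy = net.Wh.t() * mat(dz);

  List gblocks(net.blocks.size());
  for (int b = (int)net.blocks.size() - 1; b >= 0; --b) {
    BlockG g;
    dy = block_backward(dy, net.blocks[b], caches[b], g, N, T);
    gblocks[b] = List::create(
      Named("W1") = g.dW1, Named("Wb3") = g.dWb3, Named("W3") = g.dW3,
      Named("Wb5") = g.dWb5, Named("W5") = g.dW5,
      Named("Wb7") = g.dWb7, Named("W7") = g.dW7, Named("Wr") = g.dWr,
      Named("gi") = g.dgi, Named("bi") = g.dbi,
      Named("gr") = g.dgr, Named("br") = g.dbr);
  }
  return List::create(Named("loss") = loss,
                      Named("blocks") = gblocks,
                      Named("head") = List::create(Named("W") = dWh,
                                                   Named("b") = dbh));
}

// ---------------------------------------------------------------------------
// exported: training loop with early stopping

// [[Rcpp::export(name = ".cpp_train")]]
List cpp_train(List weights,
               Rcpp::NumericVector Xtr, Rcpp::NumericMatrix Ytr,
               Rcpp::NumericVector Xva, Rcpp::NumericMatrix Yva,
               double lr, int batch_size, int max_epochs, int patience,
               double bn_momentum = 0.1, bool verbose = false) {
  Rcpp::RNGScope rng_scope;  // minibatch shuffling uses R's RNG
  Net net = parse_net(weights);

  int Ntr, C, T, Nva, Cva, Tva;
  mat Xall = unpack_windows(Xtr, Ntr, C, T);
  rowvec Yall = unpack_labels(Ytr);
  mat Xval = unpack_windows(Xva, Nva, Cva, Tva);
  rowvec Yval = unpack_labels(Yva);
  if (Tva != T || Cva != C) stop("train and validation window shapes differ");

  std::vector<mat*> pm; std::vector<vec*> pv;
  collect_params(net, pm, pv);
  Adam adam; adam.lr = lr; adam.init(pm, pv);

  std::vector<double> tr_hist, va_hist;
  double best_val = datum::inf;
  int best_epoch = 0, since = 0, epochs_run = 0;
  Net best = net;

  std::vector<int> order(Ntr);
  for (int i = 0; i < Ntr; ++i) order[i] = i;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    // Fisher-Yates with R's RNG for reproducibility under set.seed()
    for (int i = Ntr - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double ep_loss = 0.0;
    for (int lo = 0; lo < Ntr; lo += batch_size) {
      int hi = std::min(lo + batch_size, Ntr);
      int B = hi - lo;
      mat xb(C, (size_t)B * T);
      rowvec yb((size_t)B * T);
      for (int i = 0; i < B; ++i) {
        int w = order[lo + i];
        xb.cols((size_t)i * T, (size_t)(i + 1) * T - 1) =
          Xall.cols((size_t)w * T, (size_t)(w + 1) * T - 1);
        yb.subvec((size_t)i * T, (size_t)(i + 1) * T - 1) =
          Yall.subvec((size_t)w * T, (size_t)(w + 1) * T - 1);
      }
      std::vector<BlockCache> caches;
      mat y_last;
      rowvec z = net_logits_train(net, xb, B, T, bn_momentum, caches, y_last);
      rowvec dz;
      double loss = bce_with_logits(z, yb, &dz);
      if (!std::isfinite(loss))
        stop("training diverged (non-finite loss) at epoch %d; lower the learning rate", epoch);
      ep_loss += loss * B;

      std::vector<BlockG> gb(net.blocks.size());
      mat dWh = mat(dz) * y_last.t();
      vec dbh = vec{accu(dz)};
      mat dy = net.Wh.t() * mat(dz);
      for (int b = (int)net.blocks.size() - 1; b >= 0; --b)
        dy = block_backward(dy, net.blocks[b], caches[b], gb[b], B, T);

      std::vector<mat*> gm; std::vector<vec*> gv;
      for (BlockG& g : gb) {
        gm.push_back(&g.dW1); gm.push_back(&g.dWb3); gm.push_back(&g.dW3);
        gm.push_back(&g.dWb5); gm.push_back(&g.dW5);
        gm.push_back(&g.dWb7); gm.push_back(&g.dW7); gm.push_back(&g.dWr);
        gv.push_back(&g.dgi); gv.push_back(&g.dbi);
        gv.push_back(&g.dgr); gv.push_back(&g.dbr);
      }
      gm.push_back(&dWh);
      gv.push_back(&dbh);
      adam.step(pm, gm, pv, gv);
      Rcpp::checkUserInterrupt();
    }
    ep_loss /= (double)Ntr;
    double va_loss = eval_loss_chunked(net, Xval, Yval, Nva, T, 256);
    if (!std::isfinite(va_loss))
      stop("training diverged (non-finite validation loss) at epoch %d", epoch);
    tr_hist.push_back(ep_loss);
    va_hist.push_back(va_loss);
    epochs_run = epoch;
    if (verbose)
      Rcpp::Rcout << "epoch " << epoch << " train " << ep_loss
                  << " val " << va_loss << "\n";
    if (va_loss < best_val) {
      best_val = va_loss;
      best_epoch = epoch;
      best = net;
      since = 0;
    } else {
      ++since;
    }
    if (since >= patience) break;
  }

  return List::create(
    Named("weights") = net_to_list(best),
    Named("train_loss") = tr_hist,
    Named("val_loss") = va_hist,
    Named("best_epoch") = best_epoch,
    Named("best_val_loss") = best_val,
    Named("epochs_run") = epochs_run,
    Named("stopped_early") = (epochs_run < max_epochs));
}
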