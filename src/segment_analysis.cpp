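// Angular segment analysis on the dual (segment-adjacency) graph.
//
// For every source segment we restrict attention to segments within a METRIC
// network radius (midpoint-to-midpoint step cost (len_i + len_j)/2) and run an
// angular-cost Dijkstra on that induced subgraph. Closeness sums the minimal
// angular distances; betweenness splits flow equally across co-optimal
// angular paths (cost ties within 1e-9).
//
// Co-optimal counting matches exhaustive simple-path enumeration, including
// the delicate case of zero-cost (collinear) adjacency: segments linked by
// zero-turn edges at equal angular distance form chain "clusters" (a closed
// zero-turn loop is geometrically impossible), and a shortest path may enter
// such a chain at any node and walk along it. Path counts and betweenness
// dependencies are therefore computed per chain with entry/exit bookkeeping
// rather than by naive predecessor counting, which would either drop or
// double-count these paths.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double EPS = 1e-6;

struct Edge { int to; double ang; double met; };

typedef std::pair<double, int> QItem;  // (dist, node), min-heap

static void dijkstra(const std::vector<std::vector<Edge> >& adj,
                     int src, bool use_ang, const std::vector<char>& allowed,
                     std::vector<double>& dist) {
  int n = adj.size();
  dist.assign(n, R_PosInf);
  std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem> > pq;
  dist[src] = 0.0;
  pq.push(QItem(0.0, src));
  while (!pq.empty()) {
    QItem top = pq.top(); pq.pop();
    int u = top.second;
    if (top.first > dist[u] + EPS) continue;
    for (size_t e = 0; e < adj[u].size(); ++e) {
      int v = adj[u][e].to;
      if (!allowed.empty() && !allowed[v]) continue;
      double w = use_ang ? adj[u][e].ang : adj[u][e].met;
      double nd = dist[u] + w;
      if (nd < dist[v] - 1e-12) {
        dist[v] = nd;
        pq.push(QItem(nd, v));
      }
    }
  }
}

// [[Rcpp::export]]
List segment_analysis_cpp(int nseg, IntegerVector edge_i, IntegerVector edge_j,
                          NumericVector ang_cost, NumericVector met_cost,
                          double radius) {
  int n = nseg;
  std::vector<std::vector<Edge> > adj(n);
  for (int e = 0; e < edge_i.size(); ++e) {
    int a = edge_i[e] - 1, b = edge_j[e] - 1;
    Edge e1; e1.to = b; e1.ang = ang_cost[e]; e1.met = met_cost[e];
    Edge e2; e2.to = a; e2.ang = ang_cost[e]; e2.met = met_cost[e];
    adj[a].push_back(e1);
    adj[b].push_back(e2);
  }

  NumericVector reach_n(n), ang_sum(n), betweenness(n);
  std::vector<double> dmet, dist;
  std::vector<char> allowed;
  std::vector<char> none;  // empty = no restriction

  for (int s = 0; s < n; ++s) {
    // metric reach restriction
    dijkstra(adj, s, false, none, dmet);
    allowed.assign(n, 0);
    int nr = 0;
    for (int v = 0; v < n; ++v) {
      if (std::isfinite(dmet[v]) && dmet[v] <= radius + EPS) {
        allowed[v] = 1; ++nr;
      }
    }
    reach_n[s] = nr - 1;  // others within radius
    if (nr <= 1) { ang_sum[s] = NA_REAL; continue; }

    // angular distances on the induced subgraph
    dijkstra(adj, s, true, allowed, dist);
    double asum = 0.0;
    for (int v = 0; v < n; ++v) {
      if (allowed[v] && v != s && std::isfinite(dist[v])) asum += dist[v];
    }
    ang_sum[s] = asum;

    // --- cluster decomposition: chains of zero-turn ties -------------------
    // cluster id per node; clusters are connected components over edges with
    // angular cost <= EPS among reached nodes (their dists tie automatically)
    std::vector<int> cl(n, -1);
    std::vector<std::vector<int> > members;
    for (int v = 0; v < n; ++v) {
      if (!allowed[v] || cl[v] != -1 || !std::isfinite(dist[v])) continue;
      int id = members.size();
      members.push_back(std::vector<int>());
      // BFS over zero edges
      std::vector<int> stack(1, v);
      cl[v] = id;
      while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        members[id].push_back(u);
        for (size_t e = 0; e < adj[u].size(); ++e) {
          int w = adj[u][e].to;
          if (adj[u][e].ang <= EPS && allowed[w] && cl[w] == -1 &&
              std::isfinite(dist[w])) {
            cl[w] = id;
            stack.push_back(w);
          }
        }
      }
    }
    int ncl = members.size();

    // order each cluster as a chain (walk from an endpoint)
    std::vector<std::vector<int> > chain(ncl);
    for (int c = 0; c < ncl; ++c) {
      std::vector<int>& mem = members[c];
      if (mem.size() == 1) { chain[c] = mem; continue; }
      // zero-degree within cluster
      int start = -1;
      for (size_t k = 0; k < mem.size(); ++k) {
        int deg = 0;
        for (size_t e = 0; e < adj[mem[k]].size(); ++e) {
          if (adj[mem[k]][e].ang <= EPS && cl[adj[mem[k]][e].to] == c) ++deg;
        }
        if (deg <= 1) { start = mem[k]; break; }
      }
      if (start < 0) start = mem[0];  // defensive: should not happen (no loops)
      std::vector<char> seen(n, 0);
      std::vector<int> ord;
      int cur = start;
      seen[cur] = 1;
      ord.push_back(cur);
      bool moved = true;
      while (moved) {
        moved = false;
        for (size_t e = 0; e < adj[cur].size(); ++e) {
          int w = adj[cur][e].to;
          if (adj[cur][e].ang <= EPS && cl[w] == c && !seen[w]) {
            seen[w] = 1;
            ord.push_back(w);
            cur = w;
            moved = true;
            break;
          }
        }
      }
      chain[c] = ord;
    }

    // process clusters in increasing distance: sigma_ext per node, S per
    // cluster, sigma per node
    std::vector<int> order(ncl);
    for (int c = 0; c < ncl; ++c) order[c] = c;
    std::vector<double> cl_dist(ncl);
    for (int c = 0; c < ncl; ++c) cl_dist[c] = dist[chain[c][0]];
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return cl_dist[a] < cl_dist[b]; });

    std::vector<double> sigma_ext(n, 0.0), sigma(n, 0.0), S(ncl, 0.0);
    for (int oc = 0; oc < ncl; ++oc) {
      int c = order[oc];
      double tot = 0.0;
      for (size_t k = 0; k < chain[c].size(); ++k) {
        int v = chain[c][k];
        double se = (v == s) ? 1.0 : 0.0;
        for (size_t e = 0; e < adj[v].size(); ++e) {
          int p = adj[v][e].to;
          double w = adj[v][e].ang;
          if (w > EPS && allowed[p] && std::isfinite(dist[p]) &&
              std::fabs(dist[p] + w - dist[v]) <= EPS) {
            se += sigma[p];
          }
        }
        sigma_ext[v] = se;
        tot += se;
      }
      S[c] = tot;
      for (size_t k = 0; k < chain[c].size(); ++k) sigma[chain[c][k]] = tot;
    }

    // Dependency accumulation, clusters in decreasing distance.
    //
    // The usual Brandes composition delta(p) += sigma(p)/sigma(w)(1+delta(w))
    // assumes the through-w dependency is spread proportionally over ALL
    // sigma(w) shortest paths into w. Inside a zero-turn chain that is false:
    // only the paths that ENTER the chain at w can still walk along it. We
    // therefore propagate Delta(w), the dependency carried by one path unit
    // entering at w:
    //   Delta(u) = (#in-cluster targets != u, != source)/S_C + E_C,
    //   E_C = sum over x in C of gamma(x),
    //   gamma(x) = sum over tight external successors w of (1/sigma(w) +
    //              Delta(w)),
    // and credit interior chain nodes with entry/exit bookkeeping.
    std::vector<double> Delta(n, 0.0);
    for (int oc = ncl - 1; oc >= 0; --oc) {
      int c = order[oc];
      const std::vector<int>& ord = chain[c];
      int m = ord.size();
      std::vector<double> gamma(m, 0.0), se(m, 0.0);
      int spos = -1;
      for (int k = 0; k < m; ++k) {
        int v = ord[k];
        se[k] = sigma_ext[v];
        if (v == s) spos = k;
        for (size_t e = 0; e < adj[v].size(); ++e) {
          int w2 = adj[v][e].to;
          double w = adj[v][e].ang;
          if (w > EPS && allowed[w2] && std::isfinite(dist[w2]) &&
              std::fabs(dist[v] + w - dist[w2]) <= EPS && sigma[w2] > 0) {
            gamma[k] += 1.0 / sigma[w2] + Delta[w2];
          }
        }
      }
      double E = 0.0;
      for (int k = 0; k < m; ++k) E += gamma[k];
      for (int k = 0; k < m; ++k) {
        int v = ord[k];
        double targets = m - 1 - ((spos >= 0 && v != s) ? 1 : 0);
        Delta[v] = (S[c] > 0 ? targets / S[c] : 0.0) + E;
      }
      // prefix sums for interior crediting
      std::vector<double> se_le(m), se_ge(m), ga_le(m), ga_ge(m);
      double acc = 0.0;
      for (int k = 0; k < m; ++k) { acc += se[k]; se_le[k] = acc; }
      acc = 0.0;
      for (int k = m - 1; k >= 0; --k) { acc += se[k]; se_ge[k] = acc; }
      acc = 0.0;
      for (int k = 0; k < m; ++k) { acc += gamma[k]; ga_le[k] = acc; }
      acc = 0.0;
      for (int k = m - 1; k >= 0; --k) { acc += gamma[k]; ga_ge[k] = acc; }

      for (int r = 0; r < m; ++r) {
        int v = ord[r];
        if (v == s) continue;  // the source is never an interior node
        // (a) entry p, exit x with r on the chain between them (inclusive)
        double da = se_le[r] * ga_ge[r] + se_ge[r] * ga_le[r] - se[r] * gamma[r];
        // (b) in-cluster targets q != r with r on the walk p..q; the source
        //     position is excluded as a target
        double nb_right = m - 1 - r;           // q > r
        double nb_left = r;                    // q < r
        if (spos > r) nb_right -= 1.0;
        if (spos >= 0 && spos < r) nb_left -= 1.0;
        double db = 0.0;
        if (S[c] > 0) {
          db = (se_le[r] * nb_right + se_ge[r] * nb_left) / S[c];
        }
        betweenness[v] += da + db;
      }
    }
  }

  // ordered (j,k) pairs were accumulated; report unordered j<k
  for (int v = 0; v < n; ++v) betweenness[v] /= 2.0;

  return List::create(_["reach"] = reach_n,
                      _["ang_sum"] = ang_sum,
                      _["betweenness"] = betweenness);
}

// Cells of a regular grid whose centers lie within `width` of any of the
// given line segments (capsule distance), returned as 1-based column-major
// indices into the value matrix (row 1 = top row). Used to rasterize
// catchment and route corridors quickly.
// [[Rcpp::export]]
IntegerVector corridor_cells_cpp(double xll, double ytop, double cell,
                                 int nr, int nc,
                                 NumericVector x1, NumericVector y1,
                                 NumericVector x2, NumericVector y2,
                                 double width) {
  std::vector<char> mask((size_t)nr * nc, 0);
  for (int s = 0; s < x1.size(); ++s) {
    double ax = x1[s], ay = y1[s], bx = x2[s], by = y2[s];
    double bx0 = std::min(ax, bx) - width, bx1 = std::max(ax, bx) + width;
    double by0 = std::min(ay, by) - width, by1 = std::max(ay, by) + width;
    int c0 = std::max(0, (int)std::floor((bx0 - xll) / cell - 0.5));
    int c1 = std::min(nc - 1, (int)std::ceil((bx1 - xll) / cell - 0.5));
    int r0 = std::max(0, (int)std::floor((ytop - by1) / cell - 0.5));
    int r1 = std::min(nr - 1, (int)std::ceil((ytop - by0) / cell - 0.5));
    double vx = bx - ax, vy = by - ay;
    double len2 = vx * vx + vy * vy;
    double w2 = width * width;
    for (int c = c0; c <= c1; ++c) {
      double px = xll + (c + 0.5) * cell;
      for (int r = r0; r <= r1; ++r) {
        size_t idx = (size_t)c * nr + r;
        if (mask[idx]) continue;
        double py = ytop - (r + 0.5) * cell;
        double t = len2 > 0 ? ((px - ax) * vx + (py - ay) * vy) / len2 : 0.0;
        if (t < 0) t = 0; else if (t > 1) t = 1;
        double dx = px - (ax + t * vx), dy = py - (ay + t * vy);
        if (dx * dx + dy * dy <= w2) mask[idx] = 1;
      }
    }
  }
  std::vector<int> out;
  for (size_t i = 0; i < mask.size(); ++i) {
    if (mask[i]) out.push_back((int)i + 1);
  }
  return wrap(out);
}
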