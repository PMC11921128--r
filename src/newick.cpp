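#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <cstdlib>
#include <fstream>
#include <sstream>
#include <string>
#include <vector>

using namespace Rcpp;

// Streaming single-pass Newick reader.
//
// The tree is built directly into flat arrays while scanning the input once,
// left to right, through a fixed-size buffer.  Node identifiers are assigned
// in the order node groups open in the text, which is exactly the depth-first
// pre-order of the tree, so parent[u] < u holds for every non-root node by
// construction.  Transient state is the read buffer plus one in-flight token
// (label or length); neither grows with input size.

namespace {

class ChunkReader {
public:
  ChunkReader(std::istream& in, std::size_t bufsize)
    : in_(in), buf_(bufsize), len_(0), pos_(0) {}
  bool next(char& c) {
    if (pos_ >= len_) {
      in_.read(buf_.data(), static_cast<std::streamsize>(buf_.size()));
      len_ = static_cast<std::size_t>(in_.gcount());
      pos_ = 0;
      if (len_ == 0) return false;
    }
    c = buf_[pos_++];
    return true;
  }
private:
  std::istream& in_;
  std::vector<char> buf_;
  std::size_t len_, pos_;
};

inline bool is_ws(char c) {
  return c == ' ' || c == '\t' || c == '\n' || c == '\r' || c == '\f' || c == '\v';
}

struct ParseState {
  std::vector<double> parent;
  std::vector<std::string> label;
  std::vector<double> length;
  bool store_labels, store_lengths, single_precision;
  double null_value, capacity;
  std::size_t cur = 0;
  long depth = 0;
  int mode = 0;              // 0 = label position, 1 = length position, 2 = node done
  bool cur_has_label = false;
  bool after_close = false;  // cur's child group just closed -> '(' would be a second group
  std::string token;
  bool token_quoted = false; // completed a quoted token for cur
  std::size_t max_token = 0;
  long n_negative = 0;

  ParseState(bool sl, bool sn, bool sp, double nullv, double cap)
    : store_labels(sl), store_lengths(sn), single_precision(sp),
      null_value(nullv), capacity(cap) {
    new_node(nullv, true);
  }

  std::size_t new_node(double par, bool is_root = false) {
    if (!is_root && static_cast<double>(parent.size()) + 1.0 > capacity)
      stop("node count exceeds the capacity of the configured ID width");
    parent.push_back(par);
    if (store_labels) label.push_back(std::string());
    if (store_lengths) length.push_back(0.0);
    return parent.size() - 1;
  }

  void reset_node_state() {
    mode = 0;
    cur_has_label = false;
    after_close = false;
    token.clear();
    token_quoted = false;
  }

  void finalize_token(bool at_ws) {
    if (token.size() > max_token) max_token = token.size();
    if (mode == 0) {
      if (!token.empty() || token_quoted) {
        if (store_labels) label[cur] = token;
        cur_has_label = true;
        token.clear();
        token_quoted = false;
      }
    } else if (mode == 1) {
      if (token.empty()) {
        if (at_ws) return;  // whitespace directly after ':' — keep waiting
        stop("missing branch length after ':'");
      }
      const char* s = token.c_str();
      char* end = nullptr;
      double v = std::strtod(s, &end);
      if (end == s || *end != '\0')
        stop("unparseable branch length token '%s'", token.c_str());
      if (v < 0) ++n_negative;
      if (store_lengths)
        length[cur] = single_precision ? static_cast<double>(static_cast<float>(v)) : v;
      token.clear();
      mode = 2;
    }
  }
};

List parse_stream(std::istream& in, bool store_labels, bool store_lengths,
                  bool single_precision, double null_value, double capacity,
                  std::size_t bufsize) {
  ChunkReader rd(in, bufsize);
  ParseState st(store_labels, store_lengths, single_precision, null_value, capacity);

  bool done = false, seen_content = false;
  bool in_quote = false, quote_pending = false;
  long comment_depth = 0;
  char c;

  while (rd.next(c)) {
    if (comment_depth > 0) {
      if (c == '[') ++comment_depth;
      else if (c == ']') --comment_depth;
      continue;
    }
    if (in_quote) {
      if (quote_pending) {
        quote_pending = false;
        if (c == '\'') { st.token += '\''; continue; }
        in_quote = false;
        st.token_quoted = true;
        // fall through: reprocess c as a normal character below
      } else if (c == '\'') {
        quote_pending = true;
        continue;
      } else {
        st.token += c;
        if (st.token.size() > st.max_token) st.max_token = st.token.size();
        continue;
      }
    }
    if (done) {
      if (is_ws(c)) continue;
      stop("unexpected content after the terminating ';' (one tree per input)");
    }
    if (is_ws(c)) { st.finalize_token(true); continue; }
    seen_content = true;
    switch (c) {
    case '[':
      ++comment_depth;
      break;
    case '\'':
      if (st.mode == 0 && st.token.empty() && !st.cur_has_label && !st.token_quoted) {
        in_quote = true;
      } else {
        stop("unexpected quote character");
      }
      break;
    case '(':
      if (st.after_close || st.cur_has_label || st.mode != 0 || !st.token.empty() ||
          st.token_quoted)
        stop("unexpected '('");
      st.cur = st.new_node(static_cast<double>(st.cur));
      ++st.depth;
      st.reset_node_state();
      break;
    case ',':
      st.finalize_token(false);
      if (st.depth == 0)
        stop("',' outside parentheses");
      st.cur = st.new_node(st.parent[st.cur]);
      st.reset_node_state();
      break;
    case ')':
      st.finalize_token(false);
      if (st.depth == 0)
        stop("unbalanced ')'");
      st.cur = static_cast<std::size_t>(st.parent[st.cur]);
      --st.depth;
      st.reset_node_state();
      st.after_close = true;
      break;
    case ':':
      st.finalize_token(false);
      if (st.mode != 0)
        stop("unexpected ':'");
      st.mode = 1;
      break;
    case ';':
      st.finalize_token(false);
      if (st.depth != 0)
        stop("unbalanced parentheses: %ld group(s) left open", st.depth);
      done = true;
      break;
    default:
      if (st.mode == 0) {
        if (st.cur_has_label || st.token_quoted)
          stop("unexpected character '%c' after a complete label", c);
      } else if (st.mode == 2) {
        stop("unexpected character '%c' after a branch length", c);
      }
      st.token += c;
      break;
    }
  }

  if (in_quote && !quote_pending)
    stop("unterminated quoted label");
  if (comment_depth > 0)
    stop("unterminated '[' comment");
  if (!done) {
    if (!seen_content)
      stop("empty input: no Newick tree found");
    if (st.depth != 0)
      stop("unbalanced parentheses: %ld group(s) left open", st.depth);
    stop("missing terminating ';'");
  }

  List out = List::create(
    _["parent"] = NumericVector(st.parent.begin(), st.parent.end()),
    _["label"] = R_NilValue,
    _["length"] = R_NilValue,
    _["n_negative_lengths"] = static_cast<double>(st.n_negative),
    _["max_token_bytes"] = static_cast<double>(st.max_token),
    _["buffer_bytes"] = static_cast<double>(bufsize));
  if (store_labels) out["label"] = wrap(st.label);
  if (store_lengths) out["length"] = NumericVector(st.length.begin(), st.length.end());
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_parse_newick(std::string source, bool is_file, bool store_labels,
                      bool store_lengths, bool single_precision,
                      double null_value, double capacity, double buffer_size) {
  std::size_t bufsize = static_cast<std::size_t>(buffer_size);
  if (bufsize < 1) bufsize = 1;
  if (is_file) {
    std::ifstream in(source.c_str(), std::ios::binary);
    if (!in)
      stop("cannot open file '%s'", source.c_str());
    return parse_stream(in, store_labels, store_lengths, single_precision,
                        null_value, capacity, bufsize);
  }
  std::istringstream in(source);
  return parse_stream(in, store_labels, store_lengths, single_precision,
                      null_value, capacity, bufsize);
}

// Flat (counting-sort) child layout: children of node u are the nodes v with
// parent[v] == u, in increasing v, which is their left-to-right textual order
// under pre-order IDs.
static void flat_children(const NumericVector& parent,
                          std::vector<std::size_t>& start,
                          std::vector<std::size_t>& ids) {
  std::size_t n = parent.size();
  std::vector<std::size_t> count(n, 0);
  for (std::size_t u = 1; u < n; ++u)
    ++count[static_cast<std::size_t>(parent[u])];
  start.assign(n + 1, 0);
  for (std::size_t u = 0; u < n; ++u) start[u + 1] = start[u] + count[u];
  ids.assign(n > 0 ? n - 1 : 0, 0);
  std::vector<std::size_t> fill(start.begin(), start.end() - 1);
  for (std::size_t u = 1; u < n; ++u) {
    std::size_t p = static_cast<std::size_t>(parent[u]);
    ids[fill[p]++] = u;
  }
}

// [[Rcpp::export]]
List cpp_children_list(NumericVector parent) {
  std::vector<std::size_t> start, ids;
  flat_children(parent, start, ids);
  std::size_t n = parent.size();
  List out(n);
  for (std::size_t u = 0; u < n; ++u) {
    NumericVector kids(start[u + 1] - start[u]);
    for (std::size_t i = start[u]; i < start[u + 1]; ++i)
      kids[i - start[u]] = static_cast<double>(ids[i]);
    out[u] = kids;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_flat_children(NumericVector parent) {
  std::vector<std::size_t> start, ids;
  flat_children(parent, start, ids);
  std::size_t n = parent.size();
  NumericVector child_ids(ids.size()), off_start(n), off_end(n);
  for (std::size_t i = 0; i < ids.size(); ++i) child_ids[i] = static_cast<double>(ids[i]);
  for (std::size_t u = 0; u < n; ++u) {
    off_start[u] = static_cast<double>(start[u]);
    off_end[u] = static_cast<double>(start[u + 1]);
  }
  return List::create(_["child_ids"] = child_ids, _["start"] = off_start,
                      _["end"] = off_end);
}

// Depth-first pre-order of the nodes of a parent-array tree rooted at `root`,
// visiting children in increasing-ID order.  Returns 0-based original IDs.
// Used to renumber trees whose construction order (simulation, extraction)
// is not already a DFS pre-order.
// [[Rcpp::export]]
NumericVector cpp_dfs_order(NumericVector parent) {
  std::vector<std::size_t> start, ids;
  flat_children(parent, start, ids);
  std::size_t n = parent.size();
  NumericVector order(n);
  std::vector<std::pair<std::size_t, std::size_t> > stack;  // (node, next child slot)
  stack.push_back(std::make_pair(static_cast<std::size_t>(0), start[0]));
  std::size_t k = 0;
  order[k++] = 0;
  while (!stack.empty()) {
    std::size_t u = stack.back().first;
    std::size_t& i = stack.back().second;
    if (i < start[u + 1]) {
      std::size_t v = ids[i++];
      order[k++] = static_cast<double>(v);
      stack.push_back(std::make_pair(v, start[v]));
    } else {
      stack.pop_back();
    }
  }
  return order;
}

// depth[u] = number of edges from the root to u; single ascending sweep,
// valid because parent[u] < u.
// [[Rcpp::export]]
NumericVector cpp_node_depths(NumericVector parent) {
  std::size_t n = parent.size();
  NumericVector depth(n);
  depth[0] = 0;
  for (std::size_t u = 1; u < n; ++u)
    depth[u] = depth[static_cast<std::size_t>(parent[u])] + 1;
  return depth;
}

// [[Rcpp::export]]
NumericVector cpp_as_single(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = static_cast<double>(static_cast<float>(x[i]));
  return out;
}

static bool needs_quoting(const std::string& s) {
  for (std::size_t i = 0; i < s.size(); ++i) {
    char c = s[i];
    if (c == '(' || c == ')' || c == '[' || c == ']' || c == ':' || c == ';' ||
        c == ',' || c == '\'' || is_ws(c))
      return true;
  }
  return false;
}

static void append_label(std::string& out, const std::string& lab) {
  if (lab.empty()) return;
  if (!needs_quoting(lab)) { out += lab; return; }
  out += '\'';
  for (std::size_t i = 0; i < lab.size(); ++i) {
    if (lab[i] == '\'') out += "''";
    else out += lab[i];
  }
  out += '\'';
}

static void append_length(std::string& out, double v, int digits) {
  char buf[64];
  std::snprintf(buf, sizeof(buf), "%.*g", digits, v);
  out += ':';
  out += buf;
}

// Serialize a parent-array tree to a Newick string (iterative, no recursion).
// `digits` controls %g precision (9 round-trips single precision, 17 double).
// The root's length is written only when nonzero.
// [[Rcpp::export]]
std::string cpp_write_newick(NumericVector parent, Nullable<CharacterVector> label,
                             Nullable<NumericVector> length, int digits) {
  std::vector<std::size_t> start, ids;
  flat_children(parent, start, ids);
  bool has_lab = label.isNotNull(), has_len = length.isNotNull();
  CharacterVector lab;
  NumericVector len;
  if (has_lab) lab = label.get();
  if (has_len) len = length.get();

  std::string out;
  out.reserve(parent.size() * 8);
  std::vector<std::pair<std::size_t, std::size_t> > stack;
  stack.push_back(std::make_pair(static_cast<std::size_t>(0), start[0]));
  if (start[1] > start[0]) out += '(';
  while (!stack.empty()) {
    std::size_t u = stack.back().first;
    std::size_t& i = stack.back().second;
    if (i < start[u + 1]) {
      if (i > start[u]) out += ',';
      std::size_t v = ids[i++];
      if (start[v + 1] > start[v]) {
        out += '(';
        stack.push_back(std::make_pair(v, start[v]));
      } else {
        if (has_lab) append_label(out, std::string(lab[v]));
        if (has_len) append_length(out, len[v], digits);
      }
    } else {
      stack.pop_back();
      if (start[u + 1] > start[u]) out += ')';
      if (has_lab) append_label(out, std::string(lab[u]));
      if (has_len && (u != 0 || len[u] != 0)) append_length(out, len[u], digits);
    }
  }
  out += ';';
  return out;
}
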