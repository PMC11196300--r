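# Static HTML/JS shell of the feedback report. All data arrives via the
# embedded JSON payload; the script only draws what the payload contains.

report_template <- function() {
  paste(c(
'<!DOCTYPE html>',
'<html lang="en">',
'<head>',
'<meta charset="utf-8">',
'<title>__TITLE__</title>',
'<style>',
'body{font-family:system-ui,sans-serif;margin:0;background:#fafafa;color:#222}',
'header{background:#2b4a6f;color:#fff;padding:12px 24px}',
'h1{font-size:1.25rem;margin:0}',
'nav{display:flex;gap:4px;background:#2b4a6f;padding:0 24px}',
'nav button{border:none;padding:10px 18px;cursor:pointer;background:#3d618c;color:#fff;border-radius:6px 6px 0 0;font-size:0.95rem}',
'nav button.active{background:#fafafa;color:#222;font-weight:600}',
'main{padding:16px 24px;max-width:1080px;margin:0 auto}',
'section{background:#fff;border:1px solid #ddd;border-radius:8px;margin:14px 0;padding:14px 18px}',
'section h2{font-size:1.05rem;margin-top:0}',
'.unavailable{color:#888;font-style:italic}',
'table{border-collapse:collapse;font-size:0.85rem}',
'td,th{border:1px solid #ddd;padding:3px 8px;text-align:left}',
'th{background:#eef2f7}',
'.bar{fill:#5b8bc4}.bar.post{fill:#c48b5b}',
'.controls{margin:8px 0;display:flex;gap:14px;flex-wrap:wrap;align-items:center;font-size:0.9rem}',
'select{padding:3px}',
'#detail{border-top:1px dashed #bbb;margin-top:8px;padding-top:8px;font-size:0.88rem;min-height:1.5em}',
'.cloud span{display:inline-block;margin:2px 6px;color:#2b4a6f}',
'.legend span{display:inline-block;margin-right:10px;font-size:0.8rem}',
'.dot{display:inline-block;width:10px;height:10px;border-radius:5px;margin-right:3px}',
'</style>',
'</head>',
'<body>',
'<header><h1>__TITLE__</h1></header>',
'<nav>',
'<button id="tab-network" class="active" onclick="showTab(0)">Network &amp; Relationships</button>',
'<button id="tab-interactions" onclick="showTab(1)">Daily Interactions</button>',
'</nav>',
'<main>',
'<div id="pane-network">',
'<section id="sec-network_composition"><h2>Network composition by social role</h2><div class="body"></div></section>',
'<section id="sec-sociograms"><h2>Personal network sociograms</h2><div class="body"></div></section>',
'<section id="sec-membership_change"><h2>Network membership change</h2><div class="body"></div></section>',
'<section id="sec-alter_table"><h2>Network members: ratings and daily-life contact</h2><div class="body"></div></section>',
'</div>',
'<div id="pane-interactions" style="display:none">',
'<section id="sec-counts_quality"><h2>Interaction quantity and quality</h2>',
'<div class="controls"><label>Quality indicator: <select id="indicator-select"></select></label></div>',
'<div class="body"></div></section>',
'<section id="sec-timeline"><h2>Affect and interactions over the study period</h2>',
'<div class="controls"><label>Affect item: <select id="affect-select"></select></label>',
'<label>Partner: <select id="partner-select"></select></label>',
'<label><input type="checkbox" id="simple-toggle"> simple view</label></div>',
'<div class="body"></div><div id="detail">Click an interaction point for details.</div></section>',
'<section id="sec-wordcloud"><h2>What interactions were about</h2><div class="body"></div></section>',
'</div>',
'</main>',
'<script id="payload" type="application/json">__PAYLOAD__</script>',
'<script>',
'var P = JSON.parse(document.getElementById("payload").textContent);',
'var ROLE_COLORS = {family:"#4472c4", friend:"#70ad47", romantic_partner:"#c00000",',
'  fellow_student_or_colleague:"#ffc000", acquaintance:"#7f7f7f", other:"#9e5fc4"};',
'var STATUS_COLORS = {stable:"#9cb7d4", removed:"#d49c9c", added_during_esm:"#7fc97f", added_post:"#beaed4"};',
'function showTab(i){',
'  document.getElementById("pane-network").style.display = i===0?"":"none";',
'  document.getElementById("pane-interactions").style.display = i===1?"":"none";',
'  document.getElementById("tab-network").className = i===0?"active":"";',
'  document.getElementById("tab-interactions").className = i===1?"active":"";',
'}',
'function el(tag, attrs, parent){var e=document.createElementNS("http://www.w3.org/2000/svg",tag);',
'  for(var k in attrs) e.setAttribute(k, attrs[k]); if(parent) parent.appendChild(e); return e;}',
'function div(html){var d=document.createElement("div"); d.innerHTML=html; return d;}',
'function body(key){return document.querySelector("#sec-"+key+" .body");}',
'function markUnavailable(key, reason){',
'  body(key).innerHTML = "<p class=\'unavailable\'>Not available: "+reason+"</p>";}',
'',
'function barChart(rows, cls){',
'  var max = Math.max.apply(null, rows.map(function(r){return r.n;}).concat([1]));',
'  var h = rows.length*22+10, w=420;',
'  var svg = el("svg", {width:w, height:h});',
'  rows.forEach(function(r,i){',
'    el("rect",{x:190,y:i*22+4,width:(r.n/max)*200,height:14,"class":"bar "+cls},svg);',
'    var t=el("text",{x:185,y:i*22+15,"text-anchor":"end","font-size":"11"},svg);',
'    t.textContent=r.role||r.group;',
'    var v=el("text",{x:195+(r.n/max)*200,y:i*22+15,"font-size":"11"},svg);',
'    v.textContent=r.n;',
'  });',
'  return svg;}',
'',
'function renderComposition(){',
'  var s=P.sections.network_composition; if(!s.available){markUnavailable("network_composition",s.reason);return;}',
'  var b=body("network_composition");',
'  Object.keys(s.data).forEach(function(wv){',
'    var d=div("<h3>"+(wv==="pre"?"Before the interaction diary":"After the interaction diary")+"</h3>");',
'    d.appendChild(barChart(s.data[wv], wv)); b.appendChild(d);',
'  });}',
'',
'function sociogramSVG(nodes, ties, colorOf, labelOf){',
'  var w=460,h=380,pad=30;',
'  var svg=el("svg",{width:w,height:h});',
'  var pos={}; nodes.forEach(function(n){pos[n.alter_id]=[pad+n.x*(w-2*pad), pad+n.y*(h-2*pad)];});',
'  ties.forEach(function(t){ if(!pos[t.from]||!pos[t.to]) return;',
'    el("line",{x1:pos[t.from][0],y1:pos[t.from][1],x2:pos[t.to][0],y2:pos[t.to][1],stroke:"#ccc"},svg);});',
'  nodes.forEach(function(n){',
'    el("circle",{cx:pos[n.alter_id][0],cy:pos[n.alter_id][1],r:7,fill:colorOf(n),stroke:"#555"},svg);',
'    var t=el("text",{x:pos[n.alter_id][0]+8,y:pos[n.alter_id][1]+3,"font-size":"9"},svg);',
'    t.textContent=labelOf(n);',
'  });',
'  return svg;}',
'',
'function roleLegend(){',
'  var d=div(""); d.className="legend";',
'  Object.keys(ROLE_COLORS).forEach(function(r){',
'    var s=document.createElement("span");',
'    s.innerHTML="<span class=\'dot\' style=\'background:"+ROLE_COLORS[r]+"\'></span>"+r;',
'    d.appendChild(s);});',
'  return d;}',
'',
'function renderSociograms(){',
'  var s=P.sections.sociograms; if(!s.available){markUnavailable("sociograms",s.reason);return;}',
'  var b=body("sociograms"); b.appendChild(roleLegend());',
'  var wrap=div(""); wrap.style.display="flex"; wrap.style.flexWrap="wrap";',
'  Object.keys(s.data).forEach(function(wv){',
'    var d=div("<h3>"+wv+"-ESM network</h3>");',
'    d.appendChild(sociogramSVG(s.data[wv].nodes, s.data[wv].ties,',
'      function(n){return ROLE_COLORS[n.role]||"#999";},',
'      function(n){return n.label;}));',
'    wrap.appendChild(d);});',
'  b.appendChild(wrap);}',
'',
'function renderMembership(){',
'  var s=P.sections.membership_change;',
'  if(!s.available){markUnavailable("membership_change",s.reason);return;}',
'  var b=body("membership_change");',
'  var leg=div(""); leg.className="legend";',
'  Object.keys(STATUS_COLORS).forEach(function(st){',
'    var sp=document.createElement("span");',
'    sp.innerHTML="<span class=\'dot\' style=\'background:"+STATUS_COLORS[st]+"\'></span>"+st;',
'    leg.appendChild(sp);});',
'  b.appendChild(leg);',
'  var soc=P.sections.sociograms;',
'  if(soc.available && soc.data.post){',
'    var statusOf={}; s.data.status.forEach(function(r){statusOf[r.alter_id]=r.status;});',
'    b.appendChild(sociogramSVG(soc.data.post.nodes, soc.data.post.ties,',
'      function(n){return STATUS_COLORS[statusOf[n.alter_id]]||"#999";},',
'      function(n){return n.label;}));',
'  }',
'  var rc=s.data.role_changes;',
'  var h="<h3>Role changes</h3>";',
'  if(rc.length===0){h+="<p>No role changes between the two assessments.</p>";}',
'  else{h+="<table><tr><th>member</th><th>before</th><th>after</th></tr>";',
'    rc.forEach(function(r){h+="<tr><td>"+r.alter_id+"</td><td>"+r.role_pre+"</td><td>"+r.role_post+"</td></tr>";});',
'    h+="</table>";}',
'  b.appendChild(div(h));}',
'',
'function check(v){return v===true?"\\u2713":(v===false?"":"?");}',
'function renderAlterTable(){',
'  var s=P.sections.alter_table; if(!s.available){markUnavailable("alter_table",s.reason);return;}',
'  var h="<table><tr><th>name</th><th>role</th><th>closeness</th><th>emotional support</th>"+',
'    "<th>practical support</th><th>can be myself</th><th>discuss personal issues</th>"+',
'    "<th>interactions</th><th>mean quality</th><th>flag</th></tr>";',
'  s.data.forEach(function(r){',
'    h+="<tr><td>"+r.display_name+"</td><td>"+r.role+"</td><td>"+(r.closeness==null?"":r.closeness)+"</td>"+',
'      "<td>"+check(r.gives_emotional_support)+"</td><td>"+check(r.gives_practical_support)+"</td>"+',
'      "<td>"+check(r.can_be_myself)+"</td><td>"+check(r.discuss_personal_issues)+"</td>"+',
'      "<td>"+r.n_interactions+"</td><td>"+(r.mean_quality==null?"":(+r.mean_quality).toFixed(1))+"</td>"+',
'      "<td>"+(r.discrepancy?"close but no contact":"")+"</td></tr>";});',
'  h+="</table>";',
'  body("alter_table").appendChild(div(h));}',
'',
'function dotPlot(rows){',
'  var h=rows.length*20+30, w=520;',
'  var svg=el("svg",{width:w,height:h});',
'  var x0=170, xw=320;',
'  function X(v){return x0+(v/10)*xw;}',
'  for(var g=0; g<=10; g+=2){',
'    el("line",{x1:X(g),y1:10,x2:X(g),y2:h-18,stroke:"#eee"},svg);',
'    var t=el("text",{x:X(g)-3,y:h-5,"font-size":"9"},svg); t.textContent=g;}',
'  rows.forEach(function(r,i){',
'    var y=i*20+18;',
'    var t=el("text",{x:x0-5,y:y+3,"text-anchor":"end","font-size":"10"},svg);',
'    t.textContent=r.group_key+" (n="+r.n+")";',
'    (r.points||[]).forEach(function(p){',
'      el("circle",{cx:X(p),cy:y,r:3,fill:"#999",opacity:0.45},svg);});',
'    if(r.ci_low!=null){el("line",{x1:X(r.ci_low),y1:y,x2:X(r.ci_high),y2:y,stroke:"#2b4a6f","stroke-width":2},svg);}',
'    el("circle",{cx:X(r.mean),cy:y,r:5,fill:"#2b4a6f"},svg);',
'  });',
'  return svg;}',
'',
'function renderCountsQuality(){',
'  var s=P.sections.counts_quality;',
'  if(!s.available){markUnavailable("counts_quality",s.reason);return;}',
'  var sel=document.getElementById("indicator-select");',
'  sel.innerHTML="";',
'  (s.data.indicators||[]).forEach(function(ind){',
'    var o=document.createElement("option"); o.value=ind; o.textContent=ind;',
'    if(ind===P.options.indicator) o.selected=true; sel.appendChild(o);});',
'  sel.onchange=drawCountsQuality; drawCountsQuality();}',
'function drawCountsQuality(){',
'  var s=P.sections.counts_quality;',
'  var ind=document.getElementById("indicator-select").value || P.options.indicator;',
'  var b=body("counts_quality"); b.innerHTML="";',
'  var grid=div(""); grid.style.display="grid"; grid.style.gridTemplateColumns="1fr 1fr"; grid.style.gap="10px";',
'  var c1=div("<h3>Interactions per role</h3>"); c1.appendChild(barChart(s.data.counts_by_role,""));',
'  var nz=s.data.counts_by_partner.filter(function(r){return r.n>0;});',
'  var c2=div("<h3>Interactions per partner</h3>"); c2.appendChild(barChart(nz,""));',
'  var q=s.data.quality[ind]||{by_role:[],by_partner:[]};',
'  var c3=div("<h3>Quality per role: "+ind+"</h3>"); c3.appendChild(dotPlot(q.by_role));',
'  var c4=div("<h3>Quality per partner: "+ind+"</h3>"); c4.appendChild(dotPlot(q.by_partner));',
'  grid.appendChild(c1); grid.appendChild(c3); grid.appendChild(c2); grid.appendChild(c4);',
'  b.appendChild(grid);}',
'',
'function renderTimeline(){',
'  var s=P.sections.timeline;',
'  if(!s.available){markUnavailable("timeline",s.reason);return;}',
'  var asel=document.getElementById("affect-select"); asel.innerHTML="";',
'  (s.data.affect_items||[]).forEach(function(it){',
'    var o=document.createElement("option"); o.value=it; o.textContent=it;',
'    if(it===P.options.affect_item) o.selected=true; asel.appendChild(o);});',
'  var psel=document.getElementById("partner-select"); psel.innerHTML="";',
'  var all=document.createElement("option"); all.value=""; all.textContent="all partners"; psel.appendChild(all);',
'  var seen={};',
'  var first=s.data.series[Object.keys(s.data.series)[0]];',
'  first.event_points.forEach(function(p){(p.partner_ids||"").split(";").forEach(function(id){seen[id]=true;});});',
'  Object.keys(seen).sort().forEach(function(id){',
'    var o=document.createElement("option"); o.value=id; o.textContent=id; psel.appendChild(o);});',
'  var simple=document.getElementById("simple-toggle");',
'  simple.checked = !!P.options.simple_mode;',
'  asel.onchange=drawTimeline; psel.onchange=drawTimeline; simple.onchange=drawTimeline;',
'  drawTimeline();}',
'function drawTimeline(){',
'  var s=P.sections.timeline;',
'  var item=document.getElementById("affect-select").value;',
'  var pf=document.getElementById("partner-select").value;',
'  var simple=document.getElementById("simple-toggle").checked;',
'  var tl=s.data.series[item]; if(!tl) return;',
'  var b=body("timeline"); b.innerHTML="";',
'  var w=980,h=260,pad=40;',
'  var svg=el("svg",{width:w,height:h});',
'  var times=tl.affect_series.map(function(p){return Date.parse(p.time);})',
'    .concat(tl.event_points.map(function(p){return Date.parse(p.time);}));',
'  if(times.length===0){b.appendChild(div("<p class=\'unavailable\'>No data.</p>"));return;}',
'  var t0=Math.min.apply(null,times), t1=Math.max.apply(null,times);',
'  function X(t){return pad+(t1===t0?0.5:(Date.parse(t)-t0)/(t1-t0))*(w-2*pad);}',
'  function Y(v){return h-25-(v/10)*(h-50);}',
'  for(var g=0;g<=10;g+=5){el("line",{x1:pad,y1:Y(g),x2:w-pad,y2:Y(g),stroke:"#eee"},svg);',
'    var t=el("text",{x:5,y:Y(g)+3,"font-size":"9"},svg); t.textContent=g;}',
'  var prompts=tl.affect_series.filter(function(p){return p.source==="prompt";});',
'  var path=prompts.map(function(p,i){return (i?"L":"M")+X(p.time)+","+Y(p.value);}).join("");',
'  if(path) el("path",{d:path,fill:"none",stroke:"#999","stroke-width":1.5},svg);',
'  if(!simple){tl.affect_series.filter(function(p){return p.source==="event";})',
'    .forEach(function(p){el("circle",{cx:X(p.time),cy:Y(p.value),r:2,fill:"#bbb"},svg);});}',
'  tl.event_points.forEach(function(p){',
'    if(pf && (p.partner_ids||"").split(";").indexOf(pf)<0) return;',
'    var fill=simple?"#888":(ROLE_COLORS[p.role]||"#999");',
'    var c=el("circle",{cx:X(p.time),cy:Y(p.value),r:(!simple&&p.is_group)?6:4,fill:fill,',
'      stroke:"#333","stroke-width":0.5,cursor:"pointer"},svg);',
'    if(!simple&&p.is_group) c.setAttribute("opacity","0.8");',
'    c.addEventListener("click",function(){showDetail(p.event_id);});});',
'  b.appendChild(svg);',
'  if(!simple) b.appendChild(roleLegend());}',
'function showDetail(id){',
'  var d=P.sections.timeline.data.details[id];',
'  if(!d) return;',
'  var q=Object.keys(d.quality||{}).map(function(k){return k+": "+d.quality[k];}).join(", ");',
'  document.getElementById("detail").innerHTML=',
'    "<b>"+d.start_time+"</b> &middot; "+d.mode+" &middot; "+d.duration_min+" min &middot; "+d.location+',
'    "<br>with: "+(d.partner_names||[]).join(", ")+(d.is_group?" (group)":"")+',
'    "<br>category: "+d.category+" &middot; quality &mdash; "+q+',
'    "<br><i>"+(d.content_text||"")+"</i>";}',
'',
'function renderWordcloud(){',
'  var s=P.sections.wordcloud; if(!s.available){markUnavailable("wordcloud",s.reason);return;}',
'  var b=body("wordcloud");',
'  if(s.data.length===0){b.appendChild(div("<p class=\'unavailable\'>No interaction descriptions.</p>"));return;}',
'  var max=s.data[0].count;',
'  var d=div(""); d.className="cloud";',
'  s.data.forEach(function(r){',
'    var sp=document.createElement("span");',
'    sp.style.fontSize=(10+18*r.count/max)+"px"; sp.title=r.count;',
'    sp.textContent=r.term; d.appendChild(sp);});',
'  b.appendChild(d);}',
'',
'renderComposition(); renderSociograms(); renderMembership(); renderAlterTable();',
'renderCountsQuality(); renderTimeline(); renderWordcloud();',
'</script>',
'</body>',
'</html>'), collapse = "\n")
}
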