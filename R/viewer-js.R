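# Self-contained canvas viewer embedded into every interactive HTML
# document: 2D pan/zoom, 3D drag-to-rotate, hover tooltips, gradient or
# categorical legend. Reads the JSON island written by write_plot_html().
.viewer_js <- "
(function(){
var data=JSON.parse(document.getElementById('cellsnv-data').textContent);
var tip=document.getElementById('tip');
var root=document.getElementById('plots');
data.panels.forEach(function(panel){
  var holder=document.createElement('div');holder.className='panel';
  var h=document.createElement('h3');h.textContent=panel.title;
  if(data.show_labels!==false)holder.appendChild(h);
  var cv=document.createElement('canvas');cv.width=560;cv.height=480;
  holder.appendChild(cv);
  if(data.show_legend!==false){
    var lg=document.createElement('div');lg.style.fontSize='12px';
    if(panel.scale.type==='gradient'){
      lg.textContent='scale: '+panel.scale.lo+' \\u2013 '+
        (Math.round(panel.scale.hi*1000)/1000)+
        ' (grey = no signal)';
    }else{
      lg.textContent='categories: '+panel.scale.levels.join(', ');
    }
    holder.appendChild(lg);
  }
  root.appendChild(holder);
  var ctx=cv.getContext('2d');
  var pts=panel.points,is3d=data.dims===3;
  var rotX=0.4,rotY=0.6,zoom=1,panX=0,panY=0;
  var xs=pts.map(function(p){return p.x}),ys=pts.map(function(p){return p.y});
  var zs=is3d?pts.map(function(p){return p.z}):null;
  function lim(a){var mn=Math.min.apply(null,a),mx=Math.max.apply(null,a);
    var pad=(mx-mn)*0.05+1e-9;return[mn-pad,mx+pad];}
  var lx=lim(xs),ly=lim(ys),lz=is3d?lim(zs):null;
  var proj=new Array(pts.length);
  function draw(){
    ctx.clearRect(0,0,cv.width,cv.height);
    var w=cv.width,hh=cv.height,r=(data.point_size||4)/2+1.2;
    for(var i=0;i<pts.length;i++){
      var p=pts[i],sx,sy;
      var nx=(p.x-lx[0])/(lx[1]-lx[0])-0.5;
      var ny=(p.y-ly[0])/(ly[1]-ly[0])-0.5;
      if(is3d){
        var nz=(p.z-lz[0])/(lz[1]-lz[0])-0.5;
        var x1=nx*Math.cos(rotY)+nz*Math.sin(rotY);
        var z1=-nx*Math.sin(rotY)+nz*Math.cos(rotY);
        var y1=ny*Math.cos(rotX)+z1*Math.sin(rotX);
        sx=w/2+x1*w*0.8*zoom+panX;sy=hh/2-y1*hh*0.8*zoom+panY;
      }else{
        sx=w/2+nx*w*0.9*zoom+panX;sy=hh/2-ny*hh*0.9*zoom+panY;
      }
      proj[i]=[sx,sy];
      ctx.beginPath();ctx.arc(sx,sy,r,0,6.2832);
      ctx.fillStyle=p.c;ctx.fill();
      if(data.border){ctx.strokeStyle='#333';ctx.lineWidth=0.5;ctx.stroke();}
    }
    if(data.show_axes!==false&&!is3d){
      ctx.strokeStyle='#999';ctx.strokeRect(0.5,0.5,w-1,hh-1);
    }
  }
  var drag=false,lastX=0,lastY=0;
  cv.addEventListener('mousedown',function(e){drag=true;lastX=e.offsetX;lastY=e.offsetY;});
  window.addEventListener('mouseup',function(){drag=false;});
  cv.addEventListener('mousemove',function(e){
    if(drag){
      if(is3d){rotY+=(e.offsetX-lastX)*0.01;rotX+=(e.offsetY-lastY)*0.01;}
      else{panX+=e.offsetX-lastX;panY+=e.offsetY-lastY;}
      lastX=e.offsetX;lastY=e.offsetY;draw();return;
    }
    var best=-1,bd=36;
    for(var i=0;i<pts.length;i++){
      var dx=proj[i][0]-e.offsetX,dy=proj[i][1]-e.offsetY,d=dx*dx+dy*dy;
      if(d<bd){bd=d;best=i;}
    }
    if(best>=0){
      tip.style.display='block';
      tip.style.left=(e.clientX+10)+'px';tip.style.top=(e.clientY+10)+'px';
      var p=pts[best];
      tip.textContent=p.b+' : '+(p.v===null?'no signal':p.v);
    }else tip.style.display='none';
  });
  cv.addEventListener('wheel',function(e){
    e.preventDefault();zoom*=e.deltaY<0?1.1:0.9;draw();
  });
  draw();
});
})();
"
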