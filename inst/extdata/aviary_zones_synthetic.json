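{"imageWidth":640,"imageHeight":480,"shapes":[{"label":"tier-3","points":[[0,0],[640,0],[640,120],[0,120]],"shape_type":"polygon"},{"label":"tier-2","points":[[0,120],[640,120],[640,240],[0,240]],"shape_type":"polygon"},{"label":"tier-1","points":[[0,240],[640,240],[640,360],[0,360]],"shape_type":"polygon"},{"label":"litter","points":[[0,360],[640,360],[640,480],[0,480]],"shape_type":"polygon"},{"label":"exclude:region","points":[[500,240],[560,240],[560,480],[500,480]],"shape_type":"polygon"}]}
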