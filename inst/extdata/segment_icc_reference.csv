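segment_label,recording_id,icc_value
L1L2,2-1,0.601
L1L2,3-2,0.858
L1L2,4-1,0.389
L1L2,8-1,0.662
L1L2,11-2,0.550
L2L3,2-1,0.799
L2L3,3-2,0.615
L2L3,4-1,0.808
L2L3,8-1,0.662
L2L3,11-2,0.722
L3L4,2-1,0.577
L3L4,3-2,0.819
L3L4,4-1,0.886
L3L4,8-1,0.932
L3L4,11-2,0.694
L4L5,2-1,0.691
L4L5,3-2,0.437
L4L5,4-1,0.876
L4L5,8-1,0.917
L4L5,11-2,0.553
L5S1,2-1,0.763
L5S1,3-2,0.258
L5S1,4-1,0.750
L5S1,8-1,0.902
L5S1,11-2,0.268
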