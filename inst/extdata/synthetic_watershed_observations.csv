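reach_id,offset_m,kind,block,path_id
r00245,0.439,O,b01,r00305
r00297,0,H,b01,r00305
r00357,2.771,O,b02,r00406
r00400,0,H,b02,r00406
r00439,4.219,O,b03,r00506
r00465,0,H,b03,r00506
r00554,2.082,O,b04,r00615
r00565,0,H,b04,r00615
r00658,2.344,O,b05,r00711
r00704,0,H,b05,r00711
r00789,6.342,O,b06,r00824
r00816,0,H,b06,r00824
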