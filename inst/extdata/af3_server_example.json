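{"atom_chain_ids":["A","A","A","A","A","B","B","B","B"],"atom_res_ids":[1,1,1,2,2,1,1,2,2],"atom_plddts":[80,90,100,70,80,60,70,90,95],"token_chain_ids":["A","A","B","B"],"token_res_ids":[1,2,1,2],"token_res_names":["MET","SER","GLY","LYS"],"pae":[[0.25,2,12,13],[3,0.25,14,9],[11,15,0.25,4],[16,8,5,0.25]],"contact_probs":[[1,0.8,0.1,0.05],[0.8,1,0.2,0.3],[0.1,0.2,1,0.9],[0.05,0.3,0.9,1]],"ptm":0.83}
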