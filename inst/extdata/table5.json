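{
  "orthographic": "Este es el resultado de ese trabajo",
  "transcription": "esteselresultadodesetr(abaxo",
  "network": "fpndddgieegeeeeeigggsssssttttdeeeeedsssddggeeeeer(r(llrrrrrrrraaaaaessssssffuuuubblllllllldpptttttr(r(aaaaaaaaaaaaooooooooodddddddddddeeeeeeeeeeennngsssseeeeedppppppttr(r(r(r(aaaaaaabbboaaaaaaaaaxxxxxxxxxxxxxxxxxxooooooooafdsdddfpppp",
  "memory": "dddieeeeeeiigsssstttdeeeeesssdieeeer(r(llr(rrrrrrraaaar(ssssuuuubbllllllllptttttr(r(aaaaaaaaaaaaoooooooooddddddddddeeeeeeeeeeessseeeeppppttr(r(r(r(aaaaaaabbbaaaaaaaaxxxxxxxxxxxxxxxoooooopp",
  "simplified_network": "ndiegigstdeser(aesfubltr(r(addeensptr(r(abaxad",
  "simplified_memory": "digstdeesdier(ar(ubltr(r(addeesetr(r(abaxop"
}
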