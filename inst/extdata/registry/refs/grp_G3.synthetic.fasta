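>G3_anchor1
GFYTTVLPSVRTRDAPDVSRNQGISDACYLQAKLDHDVDKLIYMKVYGLTDDVPTWNLFCVNDGVIDADKQREEYYERAW
GNEHLDFRKMMESNRDRRQHDTVANVGTLSLCPIVEESEKKWTAQETNTFDWLTGGLHDEVFSGSPVGKYDFYETASTTI
NMRTVYANESFVVKRLRFGIGGTLTPTGPSVNEWLRVEHMNVSAKCLKTKIYKQQGQKSEIARIPLDHRGAVGDSSAHDD
RADLFCTCGMKYNLIVVLIDLVTTGTDKRATGMVPCKDCDNMVRIDQDSDLDEQFNTPQLFDSTLQYTNEPDFEREKTDG
SGCDDISSNICLGEKKLFAYTDFKGYLLGSVAILQGVLSFLVADTFEIGW
>G3_anchor2
GFYTTVLPSVRTRDAPDVSRNQGISDACYLQAKLDHDVDKLIYMKVYGLTDDVPTWNLFCVNDGVIDADKQREEYYERSW
GNEHLDFRKMMESNDDRRQHDTVANVGTLSLCPIVEEPEKKWTAQETNTFDWLTGGLHDEVFSGSPVGKYDFYETASTTI
NMRTVYANESFVVKRLRFGIHGTPTPTQPSVNEWLRVEHHNVVAKSLKTKIYKQQGQKWEIARIPLDHTGAVGDSSAHDD
RADLFCTCGMKYNLIVVLIDLVTTKTDKRVTGMVPCKDCDNMVRRDQDSDLDEQFNTPQLFDSTLQYTNEPDFEREKTDG
SGCDDISSNICLGEKKLFAGTDFKNYLLGSVAILQGVLSFLVADTFEIGW
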