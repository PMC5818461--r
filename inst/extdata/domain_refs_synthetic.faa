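>GAG|syn1
CWEELILRQKHGNYRMELQCHTRMRMVLKDGNFMKSKQVQYNNDVPNHDFDNWSFYGWGPKVAYHRVAWT
SIEWHYQGKWICFVMLTDFTVAVWEDPVNAKMEEIVQLGCSGYRRAMGDMWCAARIWKYPLNESYFCAIW
HYMIMYSLNIKQHLSCCNTEEEIATMGWVRQLWEFWRTMCWMHENIQYYSQASLITNQCHNFLTRNEPTT
CNPFMNWYRYCPSVDKLIHHHSKWTQCACVRMVYQMKEWYHVCIVWETINREMERCAEIKVSEEYEPMVN
EEQIKIASGRWRQYWPHWDYASKAKYQCVHDRNSRHKCLA
>GAG|syn2
EWEENTLRDKWGRKRMVRCCHTRMRMVLLDGNFMLEKHVQYQNPVNNHYFDNWSYYGEGPKCEYHRVAWT
WPEWEYQTKWICIVDVTHFTVAYWEWPVNFKMEEIFQLGCSGYRRAMGFMDNAARIWKYPLNISNLCAIW
HYMIMYSLNKRQHASCMNREQEISTAEWVYQACLGERNMAWMHENIFGSSQAYLITNETHFFLTKNEPTT
CNGFWTWHRYMPSQQKVKHHWSKLTDCANDREVYQMEQWPHSSIVLETINHCPERKAMWQVDEEYEPMVN
EPKIKLACNRWRQYWPHLDYASKALYQCVHDVNSVMVCNN
>PR|syn1
NAPKVLRFKMKNFHSPIAGEPHHPQWYMHEMFETEPAAMLISWLHMVHGAVLMRMWCAQDGHKDAIMVNC
WITAFNTEYKPVSWITHNTMEYGVTMTSLRPLFHGRWSVIEWFQMSAKAI
>PR|syn2
AYPKHLRFKMKNPYSPICGEPSHPQWYMHKVFEWEYAAMIIPWFHMVAGATLMRMCNIDDGHKCAIMVNC
WITAVNTFYKDDSSTRHCDMEYGYTCTDQRPLFMGRWSMPEWFQQSAGCS
>RT|syn1
EMYGTYHFFVHERMYQSFRAGMRLEINHDWLWISSLEHGRMLQECVSFIDEMRNVHNPCNWNVGAHLTHS
AWWHPGEHPEKWYYGGIEDGDEWIGTRCQDRWWQNRGRTPQSRAHGKTNYFMTSGTDITKWGPMADFWYN
PQKHQKGFTFNLCVLTILMWHAEYQIDIDEDFFQVQEYKRDMPVAWLVNNLIANHKIADLNRCDVDMVTV
IIWMPCFQAGYMPHIDQHSHENRGSMTDQEMIREPVNTNDFNPKDWACFM
>RT|syn2
IMYFTHHFFNHNRPVGSFRAQMRGEIGCDKLWITSLAHGRMLKEWVSFEDMGTNVHTPCHWNVGGHLTRS
HWYHPGEHPEKPYYGGIDTMFEWIGVRCQDRKMQNAGRTPQNRAHGPTNYQHDSGTLITKWGPMADQWYV
YQKHVKGFTFNKKKLFILMTHAVEQIDGDDDFLQVQAYFRIMPIAWLNHNLIANRKYADCNRCDHDMFTE
DDWMSCFQACYMPNIDQHSNCTNGNMTMCEMIREPVNPNMFYHDDWACFM
>RH|syn1
KTKKIPRLMVHVKWDAMFYSAYDKYMEMHSPCYPRPPVLFQSINWHFIYLFLCQQTTILHIYTLGIWAWG
GCFPQAVWRMNVSPITLPPQQPGDYTPVLPEILIKFWDGFHRSPHEGTAGPQRMPVYQTIHCGQPNEFGA
YFFPVRPDIN
>RH|syn2
YTEKILRLMVHCKWDASFYSAYDVYLCMVSPCYPRPMFMFQCINWHFIYLFLCSQTIILHIYTLVIWARN
FNFPQAVMWGNVPRQTLIPQQPGDYTPVLCEILLKFWDGTYRKPAEGEAGHQVIPVCDDWHSGQPNYFGF
NFFPVDPLID
>INT|syn1
GSPLFQYYTYENMEIFFIKAKFLLFRRFHLIHIKWQSRYQNLSEFFDWEVLACFPGVWWQNCYWWHRHPY
HVHGRWDTVFRHSRQNIYTDQNLFVGKPCCGNTNIQLWWENSYSVPEIWGPHFPGMEWMAMHAYQDWDVD
SQLRIREHDQPCKHTDDKWMWFKIVSQYWHNCSQDKLLIKDWSPCKRHFQELNGMPYRMDKMHQAWGVPK
GLDIEASEWQQKMRHVPQDILSTFHSTHGYQDKNWWIDKFHAGVYNIGRITHEIDGQDDDELAYTLKYPW
>INT|syn2
GSELFQWYTYYNMETEFGKWKVYLARREFLCHIFWQSIYQNDNLFFDWERLMCFPLNWWQDCYESIRHPY
HVHFRWDTVARHSRQPIYIDQNVFTGKPCCGITNIQLWWEASWSVTEFWGPCFRSMFWMAMHAYTDHDVD
SQNYIPIHYQPAHHEDDKSMEFKIHSQYWHNCQQDKLQIKDWSPCKRDFLFLNQMPYRQDNMIQMCWVPK
GTDPSASEIVQKMPHVQQMVSSYFHSVLMYQDKWWWIHTFHAGVIHYGVIIGQIDGQDDVHLFYNLKYDW
>CHROMO|syn1
SRRLFTPIYQFWDQEFFCGTYTCPCMTKNIFCNMPFMATKASFWTCEDRSWPCIRWRDTQ
>CHROMO|syn2
SRRDFTPIYQFRDWEFFCGNNTIPCMEKHGKYNTPAMATNASNWVCEWRRWPAIGWRDGQ
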